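# End-to-end orchestration: scan -> classify -> conservation ->
# comparative -> Ks -> expression, with a manifest of outputs and
# summary tables.

#' Build and validate a pipeline run configuration
#'
#' @param species named list; each element is a list with paths
#'   `proteins` (FASTA), `domains` (InterProScan-style TSV), `gff`
#'   (GFF3) and optionally `cds` (per-gene CDS FASTA).
#' @param counts,design,lengths,go optional expression-stage paths
#'   (counts TSV, design TSV, gene-length TSV, GO TSV).
#' @param contrasts data.frame (condition, control) of expression
#'   contrasts; defaults to every non-control condition vs `control`.
#' @param classifier a [classifier_config()].
#' @param thresholds named list of numeric thresholds; defaults:
#'   evalue 1e-5, ks_speciation c(0.3, 0.1), ks_retention 3, lfc 1,
#'   padj 0.05, fdr 0.01, min_block 5, max_rank_gap 25, max_gene_gap 10.
#' @param seed integer seed for the stochastic stages (clustering
#'   restarts).
#' @param out_dir output directory for stage TSVs and the manifest.
#' @return list of class `erf_run_config`.
#' @export
run_config <- function(species, counts = NULL, design = NULL,
                       lengths = NULL, go = NULL, contrasts = NULL,
                       classifier = classifier_config(),
                       thresholds = list(), seed = 1L,
                       out_dir = tempfile("erfkit_run_")) {
  def <- list(evalue = 1e-5, ks_speciation = c(0.3, 0.1), ks_retention = 3,
              lfc = 1, padj = 0.05, fdr = 0.01, min_block = 5L,
              max_rank_gap = 25L, max_gene_gap = 10L)
  def[names(thresholds)] <- thresholds
  cfg <- structure(list(species = species, counts = counts, design = design,
                        lengths = lengths, go = go, contrasts = contrasts,
                        classifier = classifier, thresholds = def,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "erf_run_config")
  # fail early, naming the stage that needs the missing input
  for (sp in names(species)) {
    s <- species[[sp]]
    if (is.null(s$proteins) || !file.exists(s$proteins))
      stopf("scan stage: protein FASTA missing for species %s", sp)
    if (is.null(s$domains) || !file.exists(s$domains))
      stopf("scan stage: domain TSV missing for species %s", sp)
    if (is.null(s$gff) || !file.exists(s$gff))
      stopf("comparative stage: GFF3 missing for species %s", sp)
    if (!is.null(s$cds) && !file.exists(s$cds))
      stopf("ks stage: CDS FASTA missing for species %s", sp)
  }
  for (nm in c("counts", "design", "lengths", "go")) {
    p <- cfg[[nm]]
    if (!is.null(p) && !file.exists(p))
      stopf("expression stage: %s file missing (%s)", nm, p)
  }
  cfg
}

#' @noRd
stage_write <- function(df, stage, name, out_dir, manifest) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  write_tsv0(df, path)
  rbind(manifest, data.frame(stage = stage, file = basename(path),
                             rows = nrow(df),
                             md5 = unname(tools::md5sum(path)),
                             stringsAsFactors = FALSE))
}

#' Run the full pipeline
#'
#' Executes scan, classify, conservation, comparative, Ks and (when
#' count data are configured) expression stages in order. Every stage's
#' table is written under the configured output directory and listed in
#' a manifest with its md5 checksum and row count; rerunning with the
#' same configuration and seed reproduces identical checksums.
#'
#' @param config an [run_config()] object.
#' @return list of class `erf_run`: `manifest`, plus the in-memory
#'   stage results (`architectures`, `calls`, `conservation`, `blocks`,
#'   `specificity`, `tandem`, `ks`, `degs`, `clusters`, `enrichment`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "erf_run_config"))
  th <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(), file = character(),
                         rows = integer(), md5 = character(),
                         stringsAsFactors = FALSE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }

  # ---- scan: parse + filter domain hits ------------------------------
  proteins <- list()
  archs <- list()
  loci <- list()
  arch_rows <- NULL
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    proteins[[sp]] <- stage("scan", readAAStringSet(s$proteins))
    hits <- stage("scan", parse_interproscan_tsv(s$domains))
    by_gene <- split_hits_by_gene(hits)
    archs[[sp]] <- stage("scan", lapply(by_gene, filter_hits,
                                        max_evalue = th$evalue))
    loci[[sp]] <- stage("comparative",
                        read_gene_loci(s$gff, species = sp))
    for (a in archs[[sp]])
      arch_rows <- rbind(arch_rows,
                         data.frame(species = sp, gene = a$gene,
                                    n_AP2 = a$n_AP2, has_B3 = a$has_B3,
                                    stringsAsFactors = FALSE))
  }
  manifest <- stage_write(arch_rows, "scan", "architectures",
                          config$out_dir, manifest)
  res$architectures <- archs

  # ---- classify ------------------------------------------------------
  calls <- NULL
  for (sp in names(config$species)) {
    cl <- stage("classify", classify_genes(proteins[[sp]], archs[[sp]],
                                           config$classifier))
    cl <- cbind(species = sp, cl)
    calls <- rbind(calls, cl)
  }
  manifest <- stage_write(calls, "classify", "family_calls",
                          config$out_dir, manifest)
  res$calls <- calls

  # ---- conservation over all single-domain alignments ----------------
  cons <- stage("conservation", {
    model <- ap2_model()
    aligned <- character(0)
    for (sp in names(config$species)) {
      pr <- setNames(as.character(proteins[[sp]]), names(proteins[[sp]]))
      for (a in archs[[sp]]) {
        ap2 <- a$hits[a$hits$kind == "AP2", , drop = FALSE]
        if (nrow(ap2) == 0) next
        dom <- substr(pr[[a$gene]], ap2$start[1], ap2$end[1])
        al <- align_to_model(dom, model)
        if (!al$unalignable) {
          r <- al$model_residues
          r[is.na(r)] <- "-"
          aligned <- c(aligned, paste(r, collapse = ""))
        }
      }
    }
    prof <- consensus_calling(column_frequencies(aligned))
    division_consensus_ratio(prof)
  })
  manifest <- stage_write(cons, "conservation", "division_ratios",
                          config$out_dir, manifest)
  res$conservation <- cons

  # ---- comparative: RBH, blocks, specificity, tandem -----------------
  fam_genes <- calls[, c("gene", "species", "subgroup")]
  fam_prot <- lapply(names(config$species), function(sp) {
    pr <- proteins[[sp]]
    pr[names(pr) %in% fam_genes$gene[fam_genes$species == sp]]
  })
  names(fam_prot) <- names(config$species)
  sps <- names(config$species)
  blocks <- list()
  block_rows <- NULL
  if (length(sps) >= 2) {
    for (i in seq_len(length(sps) - 1)) {
      for (j in (i + 1):length(sps)) {
        a <- sps[i]
        b <- sps[j]
        pairs <- stage("comparative", rbh_orthologs(fam_prot[[a]],
                                                    fam_prot[[b]]))
        la <- rerank_loci(loci[[a]], names(fam_prot[[a]]))
        lb <- rerank_loci(loci[[b]], names(fam_prot[[b]]))
        bl <- stage("comparative",
                    collinear_blocks(pairs, la, lb,
                                     min_block = th$min_block,
                                     max_rank_gap = th$max_rank_gap))
        blocks[[paste(a, b, sep = "|")]] <- bl
        if (nrow(bl))
          block_rows <- rbind(block_rows,
                              cbind(species_pair = paste(a, b, sep = "|"),
                                    bl))
      }
    }
    if (is.null(block_rows))
      block_rows <- data.frame(species_pair = character(),
                               block = integer(), geneA = character(),
                               geneB = character(),
                               stringsAsFactors = FALSE)
    manifest <- stage_write(block_rows, "comparative", "collinear_blocks",
                            config$out_dir, manifest)
    res$blocks <- blocks
    if (length(sps) >= 3) {
      spec <- stage("comparative",
                    specificity_status(blocks[1:3], fam_genes))
      manifest <- stage_write(spec$status, "comparative", "specificity",
                              config$out_dir, manifest)
      res$specificity <- spec
    }
  }
  tand <- NULL
  for (sp in sps) {
    ta <- stage("comparative",
                tandem_arrays(calls[calls$species == sp, ], loci[[sp]],
                              max_gene_gap = th$max_gene_gap))
    if (nrow(ta)) tand <- rbind(tand, cbind(species = sp, ta))
  }
  if (is.null(tand))
    tand <- data.frame(species = character(), array = integer(),
                       chrom = character(), subgroup = character(),
                       gene = character(), rank = integer(),
                       stringsAsFactors = FALSE)
  manifest <- stage_write(tand, "comparative", "tandem_arrays",
                          config$out_dir, manifest)
  res$tandem <- tand

  # ---- ks: within-species duplicates ---------------------------------
  ks_rows <- NULL
  for (sp in sps) {
    s <- config$species[[sp]]
    if (is.null(s$cds)) next
    cds <- stage("ks", readDNAStringSet(s$cds))
    dups <- stage("ks", duplicate_pairs(fam_prot[[sp]], loci[[sp]],
                                        max_gene_gap = th$max_gene_gap))
    if (nrow(dups) == 0) next
    for (i in seq_len(nrow(dups))) {
      est <- stage("ks", {
        ca <- codon_align(cds[[dups$gene1[i]]], cds[[dups$gene2[i]]])
        ng86_ks(ca$codons1, ca$codons2, dups$gene1[i], dups$gene2[i])
      })
      est$species <- sp
      est$mode <- dups$mode[i]
      ks_rows <- rbind(ks_rows, est)
    }
  }
  if (!is.null(ks_rows)) {
    ks_rows <- classify_recency(ks_rows, thresholds = th$ks_speciation,
                                retention_max = th$ks_retention)
  } else {
    ks_rows <- data.frame(gene1 = character(), gene2 = character(),
                          Ks = numeric(), recency = character(),
                          retained = logical(), stringsAsFactors = FALSE)
  }
  manifest <- stage_write(ks_rows, "ks", "ks_estimates",
                          config$out_dir, manifest)
  res$ks <- ks_rows

  # ---- expression ----------------------------------------------------
  if (!is.null(config$counts)) {
    expr <- stage("expression", {
      cdf <- read_tsv0(config$counts)
      counts <- as.matrix(cdf[, -1, drop = FALSE])
      rownames(counts) <- cdf[[1]]
      design <- read_tsv0(config$design)
      ldf <- read_tsv0(config$lengths)
      lens <- setNames(ldf$length, ldf$gene)
      contrasts <- config$contrasts %||%
        data.frame(condition = setdiff(unique(design$condition), "control"),
                   control = "control", stringsAsFactors = FALSE)
      degs <- NULL
      for (i in seq_len(nrow(contrasts))) {
        d <- call_degs(counts, lens, design, contrasts$condition[i],
                       contrasts$control[i], lfc_min = th$lfc,
                       padj_max = th$padj)
        degs <- rbind(degs, d)
      }
      list(counts = counts, design = design, lens = lens, degs = degs,
           contrasts = contrasts)
    })
    manifest <- stage_write(expr$degs, "expression", "degs",
                            config$out_dir, manifest)
    res$degs <- expr$degs

    # cluster the DEG time courses of each contrast condition
    clus_rows <- NULL
    res$clusters <- list()
    fk <- fpkm(expr$counts, expr$lens)
    for (cond in unique(expr$contrasts$condition)) {
      d <- expr$degs[expr$degs$condition == cond &
                     expr$degs$call != "none", ]
      if (nrow(d) < 4) next
      tms <- sort(unique(expr$design$time[expr$design$condition == cond &
                                          !is.na(expr$design$time)]))
      if (length(tms) < 2) next
      prof <- sapply(tms, function(tm) {
        sel <- expr$design$sample[expr$design$condition == cond &
                                  expr$design$time %in% tm]
        rowMeans(fk[d$gene, sel, drop = FALSE])
      })
      rownames(prof) <- d$gene
      cl <- stage("expression",
                  cluster_profiles(prof, k = min(4L, nrow(prof)),
                                   seed = config$seed))
      res$clusters[[cond]] <- cl
      clus_rows <- rbind(clus_rows,
                         data.frame(condition = cond,
                                    gene = names(cl$cluster),
                                    cluster = unname(cl$cluster),
                                    stringsAsFactors = FALSE))
    }
    if (!is.null(clus_rows)) {
      manifest <- stage_write(clus_rows, "expression", "clusters",
                              config$out_dir, manifest)
      res$cluster_table <- clus_rows
    }

    if (!is.null(config$go) && !is.null(clus_rows)) {
      ann <- read_tsv0(config$go)
      names(ann)[1:2] <- c("gene", "term")
      enr <- NULL
      for (cond in unique(clus_rows$condition)) {
        sub <- clus_rows[clus_rows$condition == cond, ]
        for (k in sort(unique(sub$cluster))) {
          e <- stage("expression",
                     go_enrichment(sub$gene[sub$cluster == k],
                                   rownames(expr$counts), ann,
                                   fdr_max = th$fdr))
          if (nrow(e))
            enr <- rbind(enr, cbind(condition = cond, cluster = k,
                                    e[e$rank <= 5, ]))
        }
      }
      if (!is.null(enr)) {
        manifest <- stage_write(enr, "expression", "go_enrichment",
                                config$out_dir, manifest)
        res$enrichment <- enr
      }
    }
  }

  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  write_tsv0(cbind(manifest, seed = config$seed), manifest_path)
  res$manifest <- manifest
  res$config <- config
  class(res) <- "erf_run"
  res
}

#' Summary tables of a pipeline run
#'
#' Per-species subfamily and subgroup count and proportion tables,
#' specificity counts, a Ks histogram (bin width 0.05 over retained
#' pairs) and DEG counts per condition.
#'
#' @param run an `erf_run` from [run_all()].
#' @return list of data.frames / tables.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "erf_run"))
  calls <- run$calls
  subfam <- table(calls$species, calls$subfamily)
  subgrp <- table(calls$species, calls$subgroup)
  prop <- prop.table(subfam, margin = 1)
  out <- list(subfamily_counts = subfam, subgroup_counts = subgrp,
              subfamily_proportions = prop)
  if (!is.null(run$specificity)) out$specificity <- run$specificity$counts
  if (!is.null(run$ks) && nrow(run$ks) > 0 && any(run$ks$retained)) {
    ks <- run$ks$Ks[run$ks$retained]
    out$ks_histogram <- table(cut(ks, breaks = seq(0, 3, by = 0.05),
                                  include.lowest = TRUE))
  }
  if (!is.null(run$degs)) {
    d <- run$degs[run$degs$call != "none", ]
    out$deg_counts <- table(d$condition, d$call)
  }
  out
}

#' Summaries of a published annotation count table
#'
#' Given per-species counts of previously and newly annotated family
#' genes, computes totals, the overall percentage of newly annotated
#' genes, and the per-species range. The package bundles the
#' re-annotated AP2/ERF counts for ten plant genomes as example data
#' (`system.file("extdata", "solanaceae_ap2erf_counts.tsv", package =
#' "erfkit")`).
#'
#' @param counts data.frame with columns species, previously_annotated,
#'   newly_annotated.
#' @return list with `table` (totals column and Total row appended),
#'   `total_genes`, `previously_annotated`, `newly_annotated`,
#'   `pct_newly_annotated` (rounded to the nearest percent),
#'   `min_species_total`, `max_species_total`.
#' @export
annotation_summary <- function(counts) {
  need <- c("species", "previously_annotated", "newly_annotated")
  if (!all(need %in% names(counts)))
    stopf("counts must have columns: %s", paste(need, collapse = ", "))
  counts$total <- counts$previously_annotated + counts$newly_annotated
  tot <- data.frame(species = "Total",
                    previously_annotated = sum(counts$previously_annotated),
                    newly_annotated = sum(counts$newly_annotated),
                    total = sum(counts$total))
  list(table = rbind(counts, tot),
       total_genes = tot$total,
       previously_annotated = tot$previously_annotated,
       newly_annotated = tot$newly_annotated,
       pct_newly_annotated = round(100 * tot$newly_annotated / tot$total),
       min_species_total = min(counts$total),
       max_species_total = max(counts$total))
}

#' @export
print.erf_run <- function(x, ...) {
  cat(sprintf("<erfkit run: %d stages, %d output files in %s>\n",
              length(unique(x$manifest$stage)), nrow(x$manifest),
              x$config$out_dir))
  invisible(x)
}
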