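# Synthetic-data generator.
#
# Emits labeled inputs for every downstream stage: proteomes with planted
# AP2/B3 domains (diagnostic residues set per true label, the AP2-subfamily
# 10-residue insertion, tandem arrays, cross-species collinear gene order),
# InterProScan-style domain TSVs with injected decoy and overlapping hits,
# GFF3 gene models, CDS duplicate pairs with calibrated synonymous
# divergence, negative-binomial count matrices with planted fold changes,
# and GO annotations with one planted enriched term. All randomness flows
# from the single seed in the configuration, so identical configurations
# produce byte-identical files.

#' Configuration of the synthetic-data generator
#'
#' The defaults emulate a three-species Solanaceae-like study: ~150
#' family genes per species, an ERF-dominated subgroup mix, tandem B2/B3
#' arrays on chromosomes 1 and 4 of the first species, 30% of genes
#' without orthologs, and synonymous divergences spanning the speciation
#' reference points (0.05-0.5).
#'
#' @param n_species number of species (first three are labelled ca, sl,
#'   st after pepper, tomato and potato).
#' @param genes_per_species AP2/ERF family genes per species.
#' @param subgroup_mix named proportions over the 12 subgroups (sums
#'   to 1).
#' @param subfamily_mix optional named proportions over the 6
#'   subfamilies; when supplied it overrides `subgroup_mix` by splitting
#'   each subfamily evenly over its subgroups.
#' @param tandem_arrays list of arrays planted in the first species;
#'   each element is `list(chrom=, subgroup=, size=)`.
#' @param collinear_block_fraction fraction of shared genes kept in
#'   conserved cross-species order.
#' @param species_specific_fraction fraction of genes per species with
#'   no ortholog (tandem-array genes count towards it).
#' @param ks_targets per-pair target synonymous divergences
#'   (substitutions per synonymous site) for [generate_cds_pairs()].
#' @param de_effects optional data.frame (gene, condition, lfc, shape)
#'   of planted expression effects; `NULL` lets [generate_counts()]
#'   plant a default set.
#' @param replicates biological replicates per condition/time.
#' @param background_spacing number of undomained background genes
#'   interleaved after each family gene (or tandem array) along every
#'   chromosome. Family genes in real genomes are sparse; the default
#'   of 12 keeps unrelated same-subgroup genes farther apart than the
#'   tandem-array gap rule while planted arrays stay consecutive.
#' @param domain_noise per-column probability of substituting a
#'   non-consensus residue when emitting a domain (diagnostic and
#'   subgroup-key columns are always emitted at consensus).
#' @param nb_dispersion negative-binomial dispersion of the count
#'   generator (typical bulk RNA-seq scale).
#' @param seed integer seed; fully determines every emitted byte.
#' @return list of class `truth_config`.
#' @export
truth_config <- function(n_species = 3L,
                         genes_per_species = 150L,
                         subgroup_mix = c(B1 = 0.12, B2 = 0.18, B3 = 0.10,
                                          B4 = 0.15, A1 = 0.05, A2 = 0.06,
                                          A3 = 0.05, A4 = 0.06, AP2 = 0.08,
                                          ANT = 0.05, RAV = 0.06,
                                          Soloist = 0.04),
                         subfamily_mix = NULL,
                         tandem_arrays = list(
                           list(chrom = "chr1", subgroup = "B2", size = 6L),
                           list(chrom = "chr4", subgroup = "B3", size = 5L)),
                         collinear_block_fraction = 1.0,
                         species_specific_fraction = 0.3,
                         ks_targets = c(0.05, 0.1, 0.2, 0.3, 0.5),
                         de_effects = NULL,
                         replicates = 3L,
                         background_spacing = 12L,
                         domain_noise = 0.05,
                         nb_dispersion = 0.1,
                         seed = 1L) {
  if (!is.null(subfamily_mix)) {
    check_mix(subfamily_mix, c("ERF", "DREB", "AP2", "ANT", "RAV", "Soloist"))
    sgm <- numeric(0)
    for (fam in names(subfamily_mix)) {
      members <- names(.SUBFAMILY_OF)[.SUBFAMILY_OF == fam]
      sgm[members] <- subfamily_mix[[fam]] / length(members)
    }
    subgroup_mix <- sgm[.SUBGROUPS[.SUBGROUPS %in% names(sgm)]]
  }
  check_mix(subgroup_mix, .SUBGROUPS)
  if (genes_per_species < 1) stopf("genes_per_species must be positive")
  if (n_species < 1) stopf("n_species must be positive")
  if (collinear_block_fraction < 0 || collinear_block_fraction > 1 ||
      species_specific_fraction < 0 || species_specific_fraction > 1)
    stopf("fractions must lie in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 genes_per_species = as.integer(genes_per_species),
                 subgroup_mix = subgroup_mix,
                 tandem_arrays = tandem_arrays,
                 collinear_block_fraction = collinear_block_fraction,
                 species_specific_fraction = species_specific_fraction,
                 ks_targets = ks_targets,
                 de_effects = de_effects,
                 replicates = as.integer(replicates),
                 background_spacing = as.integer(background_spacing),
                 domain_noise = domain_noise,
                 nb_dispersion = nb_dispersion,
                 seed = as.integer(seed)),
            class = "truth_config")
}

#' @noRd
check_mix <- function(mix, allowed) {
  if (is.null(names(mix)) || !all(names(mix) %in% allowed))
    stopf("mix names must be among: %s", paste(allowed, collapse = ", "))
  if (any(mix < 0) || any(mix > 1))
    stopf("mix proportions must lie in [0, 1]")
  if (abs(sum(mix) - 1) > 1e-9)
    stopf("mix proportions must sum to 1 (got %.12f)", sum(mix))
  invisible(TRUE)
}

#' @noRd
assign_mix <- function(n, mix) {
  # largest-remainder apportionment, then a seeded shuffle
  if (n == 0) return(character(0))
  base <- floor(n * mix)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * mix - base
    extra <- order(-frac, names(mix))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  labels <- rep(names(base), base)
  labels[sample.int(length(labels))]
}

#' @noRd
species_codes <- function(n) {
  base <- c("ca", "sl", "st")
  if (n <= 3) base[seq_len(n)] else c(base, sprintf("s%02d", 4:n))
}

#' @noRd
emit_domain <- function(profile_consensus, noise, fixed_cols = integer(0)) {
  chars <- strsplit(profile_consensus, "")[[1]]
  if (noise > 0) {
    flip <- runif(length(chars)) < noise
    flip[fixed_cols] <- FALSE
    for (j in which(flip)) chars[j] <- sample(setdiff(AA20, chars[j]), 1)
  }
  paste(chars, collapse = "")
}

#' @noRd
classifier_neutral_columns <- function() {
  # AP2-model columns carrying neither diagnostics, subgroup keys nor any
  # profile signature; safe to perturb without moving a gene between
  # profiles
  protected <- unique(c(14L, 19L, 49L, 56L,
                        unlist(lapply(.SUBGROUP_OVERRIDES, function(o)
                          as.integer(names(o))))))
  setdiff(seq_len(57L), protected)
}

#' @noRd
build_family_protein <- function(subgroup, noise, distinct = 0L) {
  # returns list(seq, hits = data.frame(kind, start, end)); `distinct`
  # plants that many gene-unique substitutions at classifier-neutral
  # domain columns, so genes without orthologs are farther from each
  # other than from any shared consensus gene (keeps reciprocal best
  # hits on the planted ortholog pairs)
  profs <- subgroup_profiles()
  fixed <- c(14L, 19L, 49L, 56L)
  subfam <- .SUBFAMILY_OF[[subgroup]]
  nflank <- random_peptide(sample(30:50, 1))
  cflank <- random_peptide(sample(40:70, 1))
  cons <- profs[[subgroup]]$consensus
  distinguish <- function(dom, free) {
    if (distinct <= 0L) return(dom)
    chars <- strsplit(dom, "")[[1]]
    pos <- free[sample.int(length(free), min(distinct, length(free)))]
    for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
    paste(chars, collapse = "")
  }
  neutral <- classifier_neutral_columns()
  piece <- function(dom, prev_len) {
    data.frame(kind = "AP2", start = prev_len + 1L,
               end = prev_len + nchar(dom))
  }
  if (subfam %in% c("ERF", "DREB", "Soloist")) {
    dom <- distinguish(emit_domain(cons, noise, fixed), neutral)
    seq <- paste0(nflank, dom, cflank)
    hits <- piece(dom, nchar(nflank))
  } else if (subfam %in% c("AP2", "ANT")) {
    d1 <- distinguish(emit_domain(cons, noise, fixed), neutral)
    if (subfam == "AP2") {
      d1 <- paste0(substr(d1, 1, .AP2_INSERTION_AFTER), .AP2_INSERTION,
                   substr(d1, .AP2_INSERTION_AFTER + 1, nchar(d1)))
    }
    d2 <- distinguish(emit_domain(cons, noise, fixed), neutral)
    linker <- random_peptide(sample(10:20, 1))
    seq <- paste0(nflank, d1, linker, d2, cflank)
    h1 <- piece(d1, nchar(nflank))
    h2 <- piece(d2, nchar(nflank) + nchar(d1) + nchar(linker))
    hits <- rbind(h1, h2)
  } else {  # RAV: one AP2 + one B3 domain
    dom <- distinguish(emit_domain(cons, noise, fixed), neutral)
    b3 <- distinguish(emit_domain(b3_model()$consensus, noise),
                      seq_len(nchar(.B3_BASE)))
    linker <- random_peptide(sample(10:20, 1))
    seq <- paste0(nflank, dom, linker, b3, cflank)
    hits <- rbind(piece(dom, nchar(nflank)),
                  data.frame(kind = "B3",
                             start = nchar(nflank) + nchar(dom) +
                               nchar(linker) + 1L,
                             end = nchar(nflank) + nchar(dom) +
                               nchar(linker) + nchar(b3)))
  }
  list(seq = seq, hits = hits)
}

#' @noRd
mutate_outside_domains <- function(seq, hits, n_subs) {
  if (n_subs <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  inside <- logical(length(chars))
  for (i in seq_len(nrow(hits))) inside[hits$start[i]:hits$end[i]] <- TRUE
  free <- which(!inside)
  if (length(free) == 0) return(seq)
  pos <- free[sample.int(length(free), min(n_subs, length(free)))]
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

#' @noRd
insert_at_slots <- function(base, items) {
  # insert each item (an atomic layout element: a single gene key or a
  # whole tandem-array run) at a random slot of the element list
  for (it in items) {
    slot <- sample.int(length(base) + 1L, 1L) - 1L
    base <- append(base, list(it), after = slot)
  }
  base
}

#' Generate labeled synthetic proteomes
#'
#' Produces, per species: a protein FASTA (AP2/ERF family genes with
#' planted domains plus undomained background genes), a per-gene CDS
#' FASTA (uniform reverse translation), and an InterProScan-style domain
#' TSV listing the planted hits (e-value <= 1e-6) together with injected
#' decoy hits (e-value > 1e-5) and overlapping duplicate hits, both of
#' which the downstream filter must remove.
#'
#' @param config a [truth_config()].
#' @param dir output directory (created if needed); `NULL` keeps
#'   everything in memory.
#' @return object of class `erf_truth`: `genes` (per-gene truth:
#'   species, chrom, rank, subfamily, subgroup, ortholog_group,
#'   tandem_array), `hits` (planted architectures), `proteins` / `cds`
#'   (named lists of `XStringSet`s per species), and `files` when `dir`
#'   is given.
#' @export
generate_proteomes <- function(config, dir = NULL) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(derive_seed(config$seed, 11L))
  G <- config$genes_per_species
  nsp <- config$n_species
  codes <- species_codes(nsp)
  arrays <- if (length(config$tandem_arrays)) config$tandem_arrays else list()
  arr_sizes <- vapply(arrays, function(a) as.integer(a$size), integer(1))
  n_tandem1 <- sum(arr_sizes)
  n_spec <- max(round(config$species_specific_fraction * G),
                if (length(arr_sizes)) n_tandem1 else 0L)
  n_shared <- G - n_spec
  if (n_shared < 0) stopf("tandem arrays exceed the species-specific budget")
  arr_chr_idx <- if (length(arrays))
    as.integer(sub("^chr", "", vapply(arrays, `[[`, "", "chrom"))) else
    integer(0)
  n_chr <- max(3L, arr_chr_idx)

  # subgroup labels
  shared_labels <- assign_mix(n_shared, config$subgroup_mix)
  spec_labels <- lapply(seq_len(nsp), function(s) {
    n <- if (s == 1) n_spec - n_tandem1 else n_spec
    assign_mix(n, config$subgroup_mix)
  })

  # chromosome skeleton: shared ortholog groups in fixed conserved order
  grp_ids <- if (n_shared > 0) sprintf("og%04d", seq_len(n_shared)) else
    character(0)
  grp_chr <- if (n_shared > 0)
    sort(rep(seq_len(n_chr), length.out = n_shared)) else integer(0)
  shuffled_groups <- character(0)
  if (config$collinear_block_fraction < 1 && n_shared > 0) {
    n_shuf <- floor((1 - config$collinear_block_fraction) * n_shared)
    shuffled_groups <- grp_ids[sample.int(n_shared, n_shuf)]
  }

  # layouts are lists of atomic elements per chromosome: single family
  # genes or whole tandem arrays; background genes are interleaved
  # between elements afterwards, never inside an array
  layouts <- vector("list", nsp)
  for (s in seq_len(nsp)) {
    chrs <- lapply(seq_len(n_chr), function(ci) {
      g <- grp_ids[grp_chr == ci & !(grp_ids %in% shuffled_groups)]
      as.list(if (length(g)) paste0("shared:", g) else character(0))
    })
    # displaced shared genes land at random positions
    for (g in shuffled_groups) {
      ci <- sample.int(n_chr, 1)
      chrs[[ci]] <- insert_at_slots(chrs[[ci]], list(paste0("shared:", g)))
    }
    # species-specific singles
    for (i in seq_along(spec_labels[[s]])) {
      ci <- sample.int(n_chr, 1)
      chrs[[ci]] <- insert_at_slots(chrs[[ci]],
                                    list(sprintf("spec:%d:%d", s, i)))
    }
    # tandem arrays (first species)
    if (s == 1 && length(arrays)) {
      for (ai in seq_along(arrays)) {
        ci <- arr_chr_idx[ai]
        run <- sprintf("tand:%d:%d", ai, seq_len(arr_sizes[ai]))
        chrs[[ci]] <- insert_at_slots(chrs[[ci]], list(run))
      }
    }
    layouts[[s]] <- chrs
  }

  # sequence templates
  noise <- config$domain_noise
  with_cds <- function(tpl) {
    tpl$cds <- reverse_translate(tpl$seq)
    tpl
  }
  shared_templates <- lapply(shared_labels, function(sg)
    with_cds(build_family_protein(sg, noise)))
  names(shared_templates) <- grp_ids
  shared_sg <- setNames(shared_labels, grp_ids)
  spec_templates <- lapply(seq_len(nsp), function(s)
    lapply(spec_labels[[s]], function(sg)
      with_cds(build_family_protein(sg, noise, distinct = 6L))))
  array_templates <- lapply(arrays, function(a)
    with_cds(build_family_protein(a$subgroup, noise)))

  genes <- NULL
  hits_out <- NULL
  proteins <- list()
  cds <- list()
  for (s in seq_len(nsp)) {
    code <- codes[s]
    recs <- list()
    k <- 0L
    nbg <- 0L
    for (ci in seq_len(n_chr)) {
      keys <- character(0)
      for (el in layouts[[s]][[ci]]) {
        keys <- c(keys, el)
        if (config$background_spacing > 0) {
          keys <- c(keys, sprintf("bg:%d",
                                  nbg + seq_len(config$background_spacing)))
          nbg <- nbg + config$background_spacing
        }
      }
      for (r in seq_along(keys)) {
        key <- keys[r]
        parts <- strsplit(key, ":", fixed = TRUE)[[1]]
        if (parts[1] == "bg") {
          bseq <- random_peptide(sample(150:300, 1))
          recs[[length(recs) + 1]] <- list(
            gene = sprintf("%sgene_%s", code, parts[2]),
            chrom = paste0("chr", ci), rank = r - 1L,
            subfamily = NA_character_, subgroup = NA_character_,
            ortholog_group = NA_character_, tandem_array = NA_character_,
            seq = bseq, cds = reverse_translate(bseq), hits = NULL)
          next
        }
        k <- k + 1L
        gene <- sprintf("%sAP2_%d", code, k)
        tpl_codons <- NULL
        if (parts[1] == "shared") {
          tpl <- shared_templates[[parts[2]]]
          sg <- shared_sg[[parts[2]]]
          og <- parts[2]
          ta <- NA_character_
          seq <- mutate_outside_domains(tpl$seq, tpl$hits, 3L)
          tpl_codons <- adapt_cds(split_codon_string(tpl$cds), tpl$seq, seq)
          if (s > 1) tpl_codons <- syn_jitter(tpl_codons, 8L)
        } else if (parts[1] == "spec") {
          tpl <- spec_templates[[s]][[as.integer(parts[3])]]
          sg <- spec_labels[[s]][as.integer(parts[3])]
          og <- NA_character_
          ta <- NA_character_
          seq <- tpl$seq
          tpl_codons <- split_codon_string(tpl$cds)
        } else {  # tandem
          ai <- as.integer(parts[2])
          tpl <- array_templates[[ai]]
          sg <- arrays[[ai]]$subgroup
          og <- NA_character_
          ta <- sprintf("array%d", ai)
          j <- as.integer(parts[3])
          seq <- mutate_outside_domains(tpl$seq, tpl$hits, j)
          tpl_codons <- syn_jitter(
            adapt_cds(split_codon_string(tpl$cds), tpl$seq, seq), 2L * j)
        }
        recs[[length(recs) + 1]] <- list(
          gene = gene, chrom = paste0("chr", ci), rank = r - 1L,
          subfamily = unname(.SUBFAMILY_OF[sg]), subgroup = sg,
          ortholog_group = og, tandem_array = ta,
          seq = seq, cds = paste(tpl_codons, collapse = ""),
          hits = tpl$hits)
      }
    }
    gdf <- do.call(rbind, lapply(recs, function(x)
      data.frame(gene = x$gene, species = code, chrom = x$chrom,
                 rank = x$rank, subfamily = x$subfamily,
                 subgroup = x$subgroup, ortholog_group = x$ortholog_group,
                 tandem_array = x$tandem_array,
                 length = nchar(x$seq), stringsAsFactors = FALSE)))
    genes <- rbind(genes, gdf)
    hdf <- do.call(rbind, lapply(recs, function(x) {
      if (is.null(x$hits)) return(NULL)
      data.frame(gene = x$gene, kind = x$hits$kind, start = x$hits$start,
                 end = x$hits$end, stringsAsFactors = FALSE)
    }))
    hits_out <- rbind(hits_out, hdf)
    seqs <- setNames(vapply(recs, `[[`, "", "seq"),
                     vapply(recs, `[[`, "", "gene"))
    proteins[[code]] <- AAStringSet(seqs)
    cds[[code]] <- DNAStringSet(setNames(vapply(recs, `[[`, "", "cds"),
                                         names(seqs)))
  }
  rownames(genes) <- NULL
  rownames(hits_out) <- NULL

  truth <- structure(list(config = config, species = codes, genes = genes,
                          hits = hits_out, proteins = proteins, cds = cds),
                     class = "erf_truth")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (code in codes) {
      pf <- file.path(dir, paste0(code, ".faa"))
      cf <- file.path(dir, paste0(code, ".cds.fna"))
      tf <- file.path(dir, paste0(code, "_domains.tsv"))
      writeXStringSet(proteins[[code]], pf)
      writeXStringSet(cds[[code]], cf)
      write_domain_tsv(truth, code, tf)
      files[[code]] <- list(proteins = pf, cds = cf, domains = tf)
    }
    truth$files <- files
  } else {
    # domain TSVs are part of the contract even without a directory
    truth$domain_rows <- lapply(setNames(codes, codes), function(code)
      domain_tsv_rows(truth, code))
  }
  truth
}

#' @noRd
reverse_translate <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1)]
  }, ""), collapse = "")
}

#' @noRd
adapt_cds <- function(template_codons, template_protein, protein) {
  # copies inherit the template's codon backbone; replaced residues get
  # a deterministic codon of the new amino acid
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  old <- strsplit(template_protein, "")[[1]]
  new <- strsplit(protein, "")[[1]]
  codons <- template_codons
  for (i in which(old != new)) codons[i] <- by_aa[[new[i]]][1]
  codons
}

#' @noRd
syn_jitter <- function(codons, n) {
  # sprinkle synonymous changes at four-fold third positions, so gene
  # copies carry small, recent-looking synonymous divergence
  if (n <= 0) return(codons)
  four <- which(codons %in% fourfold_codons())
  if (length(four) == 0) return(codons)
  pick <- four[sample.int(length(four), min(n, length(four)))]
  for (i in pick) {
    third <- substr(codons[i], 3, 3)
    substr(codons[i], 3, 3) <- sample(setdiff(.NT, third), 1)
  }
  codons
}

#' @noRd
split_codon_string <- function(s)
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

#' @noRd
domain_tsv_rows <- function(truth, code) {
  set.seed(derive_seed(truth$config$seed, 100L + match(code, truth$species)))
  genes <- truth$genes[truth$genes$species == code, ]
  fam <- genes[!is.na(genes$subfamily), ]
  hits <- truth$hits[truth$hits$gene %in% fam$gene, ]
  acc <- ifelse(hits$kind == "AP2", .PFAM_AP2, .PFAM_B3)
  descr <- ifelse(hits$kind == "AP2", "AP2 domain", "B3 DNA binding domain")
  ev <- 10^-runif(nrow(hits), 10, 30)
  lens <- genes$length[match(hits$gene, genes$gene)]
  rows <- data.frame(protein = hits$gene, md5 = "-", length = lens,
                     analysis = "Pfam", accession = acc,
                     description = descr, start = hits$start,
                     stop = hits$end, evalue = ev, status = "T",
                     date = "01-01-2023", stringsAsFactors = FALSE)
  # decoy hits: confidently above the e-value cutoff, random placement
  n_decoy <- max(1L, round(0.15 * nrow(fam)))
  dg <- fam[sample.int(nrow(fam), n_decoy, replace = TRUE), ]
  dstart <- vapply(dg$length, function(L) sample.int(max(L - 29L, 1L), 1L),
                   integer(1))
  decoys <- data.frame(protein = dg$gene, md5 = "-", length = dg$length,
                       analysis = "Pfam", accession = .PFAM_AP2,
                       description = "AP2 domain", start = dstart,
                       stop = pmin(dstart + 29L, dg$length),
                       evalue = 10^-runif(n_decoy, 0.5, 4.9),
                       status = "T", date = "01-01-2023",
                       stringsAsFactors = FALSE)
  # overlapping duplicates of planted hits: pass the e-value filter but
  # lose the overlap resolution to the stronger planted hit
  n_dup <- max(1L, min(nrow(rows), round(0.15 * nrow(rows))))
  di <- sample.int(nrow(rows), n_dup)
  dup <- rows[di, ]
  dup$start <- dup$start + 3L
  dup$stop <- pmin(dup$stop + 3L, dup$length)
  dup$evalue <- pmin(dup$evalue * 1e4, 1e-6)
  out <- rbind(rows, decoys, dup)
  out[order(out$protein, out$start, out$evalue), ]
}

#' @noRd
write_domain_tsv <- function(truth, code, path) {
  rows <- domain_tsv_rows(truth, code)
  write_tsv0(rows, path, col.names = FALSE)
}

#' Write GFF3 gene models matching a truth table
#'
#' One GFF3 per species; 1-based end-inclusive `gene` features whose
#' order realizes the planted ranks: tandem-array genes occupy
#' consecutive ranks, shared ortholog groups appear in conserved
#' relative order across species, species-specific genes interrupt it.
#'
#' @param config the [truth_config()] the truth was built from.
#' @param truth `erf_truth` from [generate_proteomes()].
#' @param dir output directory.
#' @return named vector of GFF3 paths.
#' @export
generate_gene_models <- function(config, truth, dir) {
  stopifnot(inherits(truth, "erf_truth"))
  if (!identical(config$seed, truth$config$seed) ||
      !identical(config$genes_per_species, truth$config$genes_per_species) ||
      !identical(config$n_species, truth$config$n_species))
    stopf("config does not match the one the truth table was built from")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (code in truth$species) {
    g <- truth$genes[truth$genes$species == code, ]
    g <- g[order(g$chrom, g$rank), ]
    start <- 1L + g$rank * 5000L
    end <- start + 3L * g$length - 1L
    lines <- c("##gff-version 3",
               sprintf("%s\terfkit\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       g$chrom, start, end, g$gene))
    path <- file.path(dir, paste0(code, ".gff3"))
    writeLines(lines, path)
    out[code] <- path
  }
  out
}

#' Generate CDS duplicate pairs with calibrated synonymous divergence
#'
#' Each pair is a random sense-codon sequence and a copy mutated only at
#' four-fold degenerate third positions, at a per-site rate chosen so
#' that the expected NG86 estimate equals the target divergence: with
#' synonymous sites S and n4 four-fold sites, each four-fold site is
#' substituted with probability pS* . S / n4 where
#' pS* = (3/4)(1 - exp(-(4/3) Ks_target)). Stop codons are never
#' created.
#'
#' @param config a [truth_config()] (`ks_targets` must be non-empty,
#'   each >= 0).
#' @param n_codons codons per sequence (default 300).
#' @param pairs_per_target replicate pairs per target (default 1).
#' @param dir optional output directory for a FASTA of all pairs.
#' @return list: `pairs` (data.frame pair, gene1, gene2, target),
#'   `cds` (named `DNAStringSet`), and `fasta` path when `dir` given.
#' @export
generate_cds_pairs <- function(config, n_codons = 300L,
                               pairs_per_target = 1L, dir = NULL) {
  stopifnot(inherits(config, "truth_config"))
  targets <- config$ks_targets
  if (length(targets) == 0) stopf("ks_targets must be non-empty")
  if (any(targets < 0)) stopf("ks_targets must be >= 0")
  set.seed(derive_seed(config$seed, 23L))
  tab <- ng86_tables()
  fourfold <- fourfold_codons()
  seqs <- DNAStringSet()
  rows <- NULL
  pid <- 0L
  for (t in targets) {
    ps_star <- (3 / 4) * (1 - exp(-(4 / 3) * t))
    if (ps_star >= 3 / 4)
      stopf("target %.3f implies pS >= 3/4; Jukes-Cantor undefined", t)
    for (r in seq_len(pairs_per_target)) {
      pid <- pid + 1L
      codons <- tab$sense[sample.int(length(tab$sense), n_codons,
                                     replace = TRUE)]
      S <- sum(tab$sites[codons])
      is4 <- codons %in% fourfold
      n4 <- sum(is4)
      p4 <- ps_star * S / n4
      if (p4 > 1)
        stopf("target %.3f needs more four-fold sites than available", t)
      mutated <- codons
      flip <- which(is4 & runif(n_codons) < p4)
      for (i in flip) {
        third <- substr(mutated[i], 3, 3)
        repl <- sample(setdiff(.NT, third), 1)
        substr(mutated[i], 3, 3) <- repl
      }
      g1 <- sprintf("pair%03d_a", pid)
      g2 <- sprintf("pair%03d_b", pid)
      add <- DNAStringSet(setNames(c(paste(codons, collapse = ""),
                                     paste(mutated, collapse = "")),
                                   c(g1, g2)))
      seqs <- c(seqs, add)
      rows <- rbind(rows, data.frame(pair = pid, gene1 = g1, gene2 = g2,
                                     target = t, n_mutated = length(flip),
                                     stringsAsFactors = FALSE))
    }
  }
  out <- list(pairs = rows, cds = seqs)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "cds_pairs.fna")
    writeXStringSet(seqs, fa)
    write_tsv0(rows, file.path(dir, "cds_pairs_truth.tsv"))
    out$fasta <- fa
  }
  out
}

#' @noRd
fourfold_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  keep <- vapply(sense, function(co) {
    stem <- substr(co, 1, 2)
    fam <- paste0(stem, .NT)
    all(gc[fam] == gc[co])
  }, logical(1))
  sense[keep]
}

#' Generate replicate count matrices with planted fold changes
#'
#' Negative-binomial counts (dispersion from the configuration) for the
#' first species' family genes plus a block of background genes, under a
#' control condition and four stresses sampled over a five-point time
#' course with the configured number of replicates. Planted effects
#' scale a gene's mean by 2^(lfc * w(shape, time)).
#'
#' @param config a [truth_config()] (`replicates >= 2`).
#' @param truth `erf_truth` from [generate_proteomes()].
#' @param dir optional output directory (counts.tsv, design.tsv,
#'   lengths.tsv, de_truth.tsv).
#' @param conditions stress conditions.
#' @param times time points (hours) per stress.
#' @param background_genes number of non-family genes in the matrix.
#' @param base_mean log-normal location of baseline expression.
#' @return list: `counts`, `design`, `lengths`, `de_truth`, and file
#'   paths when `dir` is given.
#' @export
generate_counts <- function(config, truth, dir = NULL,
                            conditions = c("cold", "heat", "salt",
                                           "mannitol"),
                            times = c(3, 6, 12, 24, 72),
                            background_genes = 800L,
                            base_mean = 150) {
  stopifnot(inherits(config, "truth_config"))
  if (config$replicates < 2) stopf("replicates must be >= 2")
  set.seed(derive_seed(config$seed, 31L))
  code <- truth$species[1]
  fam <- truth$genes$gene[truth$genes$species == code &
                          !is.na(truth$genes$subfamily)]
  bg <- sprintf("bgGene_%04d", seq_len(background_genes))
  genes <- c(fam, bg)
  lengths <- setNames(sample(600:3000, length(genes), replace = TRUE), genes)
  base <- setNames(rlnorm(length(genes), log(base_mean), 0.7), genes)

  de <- config$de_effects
  if (is.null(de)) {
    erf_genes <- truth$genes$gene[truth$genes$species == code &
                                  truth$genes$subfamily %in% "ERF"]
    pick_fam <- erf_genes[seq_len(min(12, length(erf_genes)))]
    pick_bg <- bg[seq_len(min(12, length(bg)))]
    tg <- c(pick_fam, pick_bg)
    de <- data.frame(gene = tg,
                     condition = "cold",
                     lfc = rep(c(3, -3), length.out = length(tg)),
                     shape = rep(c("flat", "early", "late", "transient"),
                                 length.out = length(tg)),
                     stringsAsFactors = FALSE)
  }
  if (is.null(de$shape)) de$shape <- "flat"
  if (!all(de$gene %in% genes))
    stopf("de_effects reference genes absent from the count matrix")

  shape_w <- function(shape, times) {
    n <- length(times)
    switch(shape,
           flat = rep(1, n),
           early = seq(1, 0.1, length.out = n),
           late = seq(0.1, 1, length.out = n),
           transient = {
             w <- rep(0.2, n)
             w[min(2, n)] <- 1
             w[min(3, n)] <- 0.6
             w
           },
           rep(1, n))
  }

  samples <- data.frame(sample = character(), condition = character(),
                        time = numeric(), replicate = integer(),
                        stringsAsFactors = FALSE)
  for (cond in c("control", conditions))
    for (tm in times)
      for (r in seq_len(config$replicates))
        samples <- rbind(samples, data.frame(
          sample = sprintf("%s_t%g_r%d", cond, tm, r), condition = cond,
          time = tm, replicate = r, stringsAsFactors = FALSE))

  counts <- matrix(0L, nrow = length(genes), ncol = nrow(samples),
                   dimnames = list(genes, samples$sample))
  disp <- config$nb_dispersion
  for (j in seq_len(nrow(samples))) {
    cond <- samples$condition[j]
    tm <- samples$time[j]
    mu <- base
    if (cond != "control") {
      eff <- de[de$condition == cond, , drop = FALSE]
      if (nrow(eff)) {
        ti <- which(times == tm)
        for (i in seq_len(nrow(eff))) {
          w <- shape_w(eff$shape[i], times)[ti]
          mu[eff$gene[i]] <- mu[eff$gene[i]] * 2^(eff$lfc[i] * w)
        }
      }
    }
    sf <- rlnorm(1, 0, 0.1)
    counts[, j] <- rnbinom(length(genes), mu = mu * sf, size = 1 / disp)
  }

  out <- list(counts = counts, design = samples, lengths = lengths,
              de_truth = de)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cdf <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    out$files <- list(
      counts = write_tsv0(cdf, file.path(dir, "counts.tsv")),
      design = write_tsv0(samples, file.path(dir, "design.tsv")),
      lengths = write_tsv0(data.frame(gene = genes,
                                      length = unname(lengths)),
                           file.path(dir, "lengths.tsv")),
      de_truth = write_tsv0(de, file.path(dir, "de_truth.tsv")))
  }
  out
}

#' Generate GO annotations with one planted enriched term
#'
#' Annotates every gene of a chosen subgroup (or an explicit gene set)
#' with the enriched term, and sprinkles background terms over all genes
#' at a uniform rate.
#'
#' @param truth `erf_truth` from [generate_proteomes()].
#' @param genes gene universe to annotate; defaults to all truth genes.
#' @param term the planted enriched GO id.
#' @param target_subgroup subgroup whose genes receive `term`.
#' @param target_genes explicit target set (overrides
#'   `target_subgroup`).
#' @param background_terms pool of background GO ids.
#' @param background_rate per gene-term annotation probability.
#' @param dir optional output directory (go.tsv).
#' @return data.frame (gene, term), plus a `file` attribute when `dir`
#'   is given.
#' @export
generate_go_annotations <- function(truth, genes = NULL,
                                    term = "GO:0050794",
                                    target_subgroup = "B2",
                                    target_genes = NULL,
                                    background_terms = sprintf("GO:%07d",
                                                               7000001:7000015),
                                    background_rate = 0.1,
                                    dir = NULL) {
  stopifnot(inherits(truth, "erf_truth"))
  if (nrow(truth$genes) == 0) stopf("empty truth table")
  set.seed(derive_seed(truth$config$seed, 41L))
  if (is.null(genes)) genes <- truth$genes$gene
  if (is.null(target_genes))
    target_genes <- truth$genes$gene[truth$genes$subgroup %in%
                                     target_subgroup]
  target_genes <- intersect(target_genes, genes)
  ann <- data.frame(gene = target_genes, term = term,
                    stringsAsFactors = FALSE)
  for (bt in background_terms) {
    hit <- genes[runif(length(genes)) < background_rate]
    if (length(hit))
      ann <- rbind(ann, data.frame(gene = hit, term = bt,
                                   stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$gene, ann$term), ]
  rownames(ann) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    attr(ann, "file") <- write_tsv0(ann, file.path(dir, "go.tsv"))
  }
  ann
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator stage into one directory: proteomes + domain
#' TSVs + per-gene CDS, GFF3 gene models, CDS duplicate pairs, count
#' matrices and GO annotations.
#'
#' @param config a [truth_config()].
#' @param dir output directory.
#' @param ks_pairs_per_target replicate CDS pairs per Ks target.
#' @return the `erf_truth` object with `files` entries for every stage.
#' @export
simulate_dataset <- function(config, dir, ks_pairs_per_target = 1L) {
  truth <- generate_proteomes(config, dir)
  gff <- generate_gene_models(config, truth, dir)
  for (code in truth$species) truth$files[[code]]$gff <- gff[[code]]
  kp <- generate_cds_pairs(config, dir = dir,
                           pairs_per_target = ks_pairs_per_target)
  counts <- generate_counts(config, truth, dir = dir)
  go <- generate_go_annotations(truth,
                                genes = rownames(counts$counts),
                                dir = dir)
  truth$files$cds_pairs <- kp$fasta
  truth$files$counts <- counts$files
  truth$files$go <- attr(go, "file")
  truth$ks_pairs <- kp$pairs
  truth$de_truth <- counts$de_truth
  truth
}

#' @export
print.erf_truth <- function(x, ...) {
  fam <- sum(!is.na(x$genes$subfamily))
  cat(sprintf("<erf_truth: %d species, %d genes (%d family), seed %d>\n",
              length(x$species), nrow(x$genes), fam, x$config$seed))
  invisible(x)
}
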