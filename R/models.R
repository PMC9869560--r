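# Bundled AP2 and B3 domain models.
#
# The package carries a compact 57-column model of the AP2/ERF DNA-binding
# domain plus one position-frequency matrix (PFM) per subgroup. These are
# used in three places: (i) the synthetic-data generator emits domain
# instances from them, (ii) scan_pssm() scores candidate windows against
# them, and (iii) the classifier falls back to nearest-profile assignment
# when diagnostic residues are uninformative. Column coordinates follow the
# usual AP2-domain convention: the two subfamily-diagnostic residues sit at
# columns 14 and 19 (Ala/Asp for ERF, Val/Glu for DREB) and the ERF
# subgroup keys at columns 49 and 56.

# base 57-residue consensus (ERF-like: A@14, D@19, F@49, L@56)
.AP2_BASE <- "SKYRGVRQRPWGKAEIRDDKRGVRVWLGTFDTAEEAARAYDEAARRFRFGDSAEVLF"

# B3 DNA-binding domain consensus (RAV subfamily second domain), width 50
.B3_BASE <- "GRLSPEWVARKMNVPESQIGEMLYVKGGKLVMFDHEGNRTWEMKYRWSDN"

# 10-residue insertion characteristic of the AP2 (vs ANT) subfamily
.AP2_INSERTION <- "GSSNQPTDGH"
.AP2_INSERTION_AFTER <- 20L  # model column the insertion follows

#' @noRd
apply_overrides <- function(base, overrides) {
  chars <- strsplit(base, "")[[1]]
  for (nm in names(overrides)) chars[as.integer(nm)] <- overrides[[nm]]
  paste(chars, collapse = "")
}

# Per-subgroup consensus overrides relative to .AP2_BASE. A-subgroups carry
# the DREB diagnostics (V@14, E@19) and distinct signature residues;
# B-subgroups differ at the key columns 49/56 (plus one signature column so
# profiles stay pairwise distinct); Soloist diverges broadly.
.SUBGROUP_OVERRIDES <- list(
  B1 = list(),
  B2 = list(`3` = "F", `49` = "L", `56` = "T"),
  B3 = list(`10` = "S", `56` = "T"),
  B4 = list(`22` = "N", `49` = "M"),
  A1 = list(`14` = "V", `19` = "E", `8` = "K"),
  A2 = list(`14` = "V", `19` = "E", `8` = "E", `25` = "I"),
  A3 = list(`14` = "V", `19` = "E", `8` = "T", `33` = "S"),
  A4 = list(`14` = "V", `19` = "E", `8` = "N", `40` = "F"),
  AP2 = list(`12` = "E", `20` = "S", `44` = "G"),
  ANT = list(`20` = "S", `44` = "G"),
  RAV = list(`5` = "A", `36` = "S"),
  Soloist = list(`2` = "P", `6` = "L", `9` = "G", `14` = "S", `15` = "Y",
                 `19` = "N", `23` = "W", `38` = "Q", `45` = "K", `52` = "N")
)

.SUBGROUPS <- names(.SUBGROUP_OVERRIDES)
.SUBFAMILY_OF <- c(B1 = "ERF", B2 = "ERF", B3 = "ERF", B4 = "ERF",
                   A1 = "DREB", A2 = "DREB", A3 = "DREB", A4 = "DREB",
                   AP2 = "AP2", ANT = "ANT", RAV = "RAV", Soloist = "Soloist")

#' @noRd
pfm_from_consensus <- function(consensus, conservation = 0.85) {
  chars <- strsplit(consensus, "")[[1]]
  w <- length(chars)
  m <- matrix((1 - conservation) / 19, nrow = 20, ncol = w,
              dimnames = list(AA20, NULL))
  for (j in seq_len(w)) m[chars[j], j] <- conservation
  m
}

#' Bundled AP2 domain model
#'
#' Returns the packaged 57-column AP2/ERF domain model: the consensus
#' string, a position-frequency matrix, and the coordinates of the
#' diagnostic (14/19) and subgroup-key (49/56) columns.
#'
#' @param conservation probability mass placed on the consensus residue at
#'   each column of the PFM.
#' @return a list with elements `consensus`, `pfm`, `width`, `kind`,
#'   `diagnostic_cols` and `key_cols`.
#' @export
ap2_model <- function(conservation = 0.85) {
  list(consensus = .AP2_BASE,
       pfm = pfm_from_consensus(.AP2_BASE, conservation),
       width = nchar(.AP2_BASE),
       kind = "AP2",
       diagnostic_cols = c(14L, 19L),
       key_cols = c(49L, 56L))
}

#' Bundled B3 domain model
#'
#' The second DNA-binding domain whose co-occurrence with an AP2 domain
#' defines the RAV subfamily.
#'
#' @inheritParams ap2_model
#' @return a list with elements `consensus`, `pfm`, `width`, `kind`.
#' @export
b3_model <- function(conservation = 0.85) {
  list(consensus = .B3_BASE,
       pfm = pfm_from_consensus(.B3_BASE, conservation),
       width = nchar(.B3_BASE),
       kind = "B3")
}

#' Per-subgroup AP2-domain profiles
#'
#' One consensus string and PFM per subgroup (A1-A4, B1-B4, AP2, ANT, RAV,
#' Soloist). These are the emission profiles of the synthetic-data
#' generator and the reference profiles of the nearest-profile classifier.
#'
#' @inheritParams ap2_model
#' @return named list; each element has `consensus`, `pfm`, `subfamily`.
#' @export
subgroup_profiles <- function(conservation = 0.85) {
  key <- paste0("subgroup_profiles_", conservation)
  if (!is.null(.erf_cache[[key]])) return(.erf_cache[[key]])
  out <- lapply(.SUBGROUPS, function(sg) {
    cons <- apply_overrides(.AP2_BASE, .SUBGROUP_OVERRIDES[[sg]])
    list(consensus = cons,
         pfm = pfm_from_consensus(cons, conservation),
         subfamily = unname(.SUBFAMILY_OF[sg]))
  })
  names(out) <- .SUBGROUPS
  .erf_cache[[key]] <- out
  out
}

#' Subfamily-level AP2-domain profiles
#'
#' Averages the subgroup PFMs within each subfamily. Used by the
#' single-domain classification fallback (nearest profile among ERF, DREB,
#' Soloist).
#'
#' @inheritParams ap2_model
#' @return named list of PFMs keyed by subfamily.
#' @export
subfamily_profiles <- function(conservation = 0.85) {
  sg <- subgroup_profiles(conservation)
  fams <- unique(unname(.SUBFAMILY_OF))
  out <- lapply(fams, function(fam) {
    members <- names(.SUBFAMILY_OF)[.SUBFAMILY_OF == fam]
    pfms <- lapply(members, function(m) sg[[m]]$pfm)
    Reduce(`+`, pfms) / length(pfms)
  })
  names(out) <- fams
  out
}

#' @noRd
profile_distance <- function(model_residues, pfm) {
  # negative mean log-likelihood over aligned model columns
  ok <- !is.na(model_residues) & model_residues %in% AA20
  if (!any(ok)) return(Inf)
  cols <- which(ok)
  -mean(log(pfm[cbind(match(model_residues[ok], AA20), cols)]))
}
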