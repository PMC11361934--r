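# Whole-sequence physicochemical descriptors.
#
# Every descriptor operates on a validated sequence: an uppercase string over
# the 20 standard one-letter amino-acid codes.  Family descriptors are
# per-residue scale-table averages; the eight scalar indices (Boman index,
# net charge, hydrophobic moment, hydrophobicity, instability index,
# isoelectric point, molecular weight, m/z) complete the 96-value vector.

#' Validate an amino-acid sequence
#'
#' Uppercases, strips whitespace, and rejects anything outside the 20
#' standard one-letter codes (so X, B, Z, U, O, `*` and digits all fail).
#'
#' @param raw Character scalar.
#' @return The cleaned sequence as a character scalar.
#' @export
#' @examples
#' validate_sequence("casslgf")
validate_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]]+", "", raw))
  if (nchar(s) == 0L) {
    stop("empty sequence", call. = FALSE)
  }
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]],
                 bad[1]), call. = FALSE)
  }
  s
}

# residue index lookup (1..20 into AA_ALPHABET); assumes validated input
.res_idx <- function(seq) {
  match(strsplit(seq, "")[[1]], AA_ALPHABET)
}

#' Average a per-residue scale over a sequence
#'
#' @param seq Validated sequence.
#' @param table Scale table from [scale_table()], or any numeric vector
#'   named by the 20 residues.
#' @return Arithmetic mean of the per-residue values.
#' @export
#' @examples
#' scale_average("AG", scale_table("KF1"))
scale_average <- function(seq, table) {
  stopifnot(all(AA_ALPHABET %in% names(table)))
  v <- as.numeric(table[AA_ALPHABET])
  mean(v[.res_idx(seq)])
}

#' Descriptors of one scale family
#'
#' @param seq Validated sequence.
#' @param family Family name, one of `names(aa_scale_families())`
#'   (e.g. `"kidera"`, `"z_scales"`, `"vhse"`).
#' @return Named numeric vector, one scale average per family dimension.
#' @export
#' @examples
#' family_descriptors("CASSLGF", "z_scales")
family_descriptors <- function(seq, family) {
  .load_scales()
  fams <- .tcrh$scales$families
  if (!family %in% names(fams)) {
    stop("unknown descriptor family: ", family, call. = FALSE)
  }
  S <- .tcrh$scales$family_matrix[, fams[[family]], drop = FALSE]
  colMeans(S[.res_idx(seq), , drop = FALSE])
}

#' Boman (protein-binding potential) index
#'
#' Mean per-residue solubility value; positive values indicate a propensity
#' to bind proteins or membranes rather than stay in solution.
#'
#' @param seq Validated sequence.
#' @return Numeric scalar.
#' @export
boman <- function(seq) {
  .load_scales()
  mean(.tcrh$scales$boman[.res_idx(seq)])
}

#' Henderson-Hasselbalch net charge
#'
#' Sums fractional charges of the N-terminus, C-terminus and ionizable side
#' chains: positive groups (N-terminus, K, R, H) contribute
#' `1 / (1 + 10^(pH - pKa))`, negative groups (C-terminus, D, E, C, Y)
#' contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param seq Validated sequence.
#' @param pH pH at which to evaluate, in `[0, 14]`.
#' @param pkas pKa set from [pka_set()].
#' @return Net charge (strictly decreasing in pH).
#' @export
#' @examples
#' net_charge("KKKK", pH = 7)
net_charge <- function(seq, pH = 7, pkas = pka_set()) {
  stopifnot(pH >= 0, pH <= 14)
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  pos_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  neg_frac <- function(pka) -1 / (1 + 10^(pka - pH))
  pos_frac(pkas[["nterm"]]) +
    sum(counts[c("K", "R", "H")] * pos_frac(pkas[c("K", "R", "H")])) +
    neg_frac(pkas[["cterm"]]) +
    sum(counts[c("D", "E", "C", "Y")] * neg_frac(pkas[c("D", "E", "C", "Y")]))
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection on `[0, 14]`.
#' For peptides with free termini the charge is positive at pH 0 and
#' negative at pH 14, so a root always exists.
#'
#' @param seq Validated sequence.
#' @param pkas pKa set from [pka_set()].
#' @param tol Width of the final bracketing interval.
#' @return pH in `[0, 14]`.
#' @export
isoelectric_point <- function(seq, pkas = pka_set(), tol = 1e-4) {
  lo <- 0
  hi <- 14
  stopifnot(net_charge(seq, lo, pkas) > 0, net_charge(seq, hi, pkas) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pkas) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean hydrophobicity
#'
#' @param seq Validated sequence.
#' @param scale_name Bundled hydrophobicity scale: `"kyte_doolittle"`
#'   (default) or `"eisenberg"`.
#' @return Mean per-residue hydrophobicity.
#' @export
hydrophobicity <- function(seq, scale_name = "kyte_doolittle") {
  .load_scales()
  h <- .tcrh$scales$hydro
  if (!scale_name %in% names(h)) {
    stop("unknown hydrophobicity scale: ", scale_name, call. = FALSE)
  }
  mean(h[[scale_name]][.res_idx(seq)])
}

#' Hydrophobic moment
#'
#' Amphipathicity index of Eisenberg: the magnitude of the vector sum of
#' per-residue hydrophobicities phased around a helical turn angle,
#' `sqrt((sum h_i sin(i * delta))^2 + (sum h_i cos(i * delta))^2) / N`
#' with `i = 0..N-1`, evaluated on sliding windows of length
#' `min(window, length)`; the maximum over windows is returned.  Uses the
#' Eisenberg consensus scale.
#'
#' @param seq Validated sequence.
#' @param angle_deg Phase angle per residue in degrees (100 for an
#'   alpha helix).
#' @param window Window length (default 11).
#' @return Maximum windowed hydrophobic moment.
#' @export
hydrophobic_moment <- function(seq, angle_deg = 100, window = 11) {
  stopifnot(window >= 1)
  .load_scales()
  h <- .tcrh$scales$hydro$eisenberg[.res_idx(seq)]
  n <- length(h)
  w <- min(window, n)
  delta <- angle_deg * pi / 180
  ang <- (seq_len(w) - 1) * delta
  s <- sin(ang)
  co <- cos(ang)
  best <- 0
  for (start in seq_len(n - w + 1L)) {
    hw <- h[start:(start + w - 1L)]
    mu <- sqrt(sum(hw * s)^2 + sum(hw * co)^2) / w
    if (mu > best) best <- mu
  }
  best
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum` of dipeptide instability weights over the `L - 1`
#' consecutive dipeptides.  Values above 40 suggest an unstable protein.
#' A length-1 sequence has no dipeptide; 0 is returned with a warning.
#'
#' @param seq Validated sequence.
#' @return Numeric scalar.
#' @export
instability_index <- function(seq) {
  idx <- .res_idx(seq)
  n <- length(idx)
  if (n < 2L) {
    warning("instability index undefined for length-1 sequences; returning 0",
            call. = FALSE)
    return(0)
  }
  W <- diwv_table()
  (10 / n) * sum(W[cbind(idx[-n], idx[-1])])
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water mass.
#'
#' @param seq Validated sequence.
#' @return Mass in daltons.
#' @export
molecular_weight <- function(seq) {
  .load_scales()
  sum(.tcrh$scales$mass[.res_idx(seq)]) + AVG_WATER_MASS
}

#' Mass-to-charge ratio
#'
#' `(M + z * m_proton) / z` for the protonated peptide at charge state `z`.
#'
#' @param seq Validated sequence.
#' @param z Charge state, integer >= 1.
#' @return m/z in daltons per unit charge.
#' @export
mass_over_charge <- function(seq, z = 1) {
  if (z < 1) stop("charge state z must be >= 1", call. = FALSE)
  (molecular_weight(seq) + z * PROTON_MASS) / z
}

# canonical names of the 8 scalar indices, in feature-vector order
SCALAR_DESCRIPTORS <- c("boman", "charge", "hydrophobic_moment",
                        "hydrophobicity", "instability", "isoelectric_point",
                        "mw", "mz")

#' The 96-descriptor vector of one sequence
#'
#' Concatenates, in canonical order, the 88 family scale averages (families
#' in the order of [aa_scale_families()]) and the 8 scalar indices: Boman
#' index, net charge at pH `charge_pH`, hydrophobic moment, hydrophobicity,
#' instability index, isoelectric point, molecular weight, and m/z.
#'
#' @param seq Sequence (validated with [validate_sequence()]).
#' @param charge_pH pH at which the scalar charge feature is evaluated.
#' @return Named numeric vector of 96 finite values.
#' @export
#' @examples
#' length(feature_vector("CASSLGQAYEQYF"))
feature_vector <- function(seq, charge_pH = 7) {
  seq <- validate_sequence(seq)
  .load_scales()
  idx <- .res_idx(seq)
  fam <- colMeans(.tcrh$scales$family_matrix[idx, , drop = FALSE])
  scalars <- c(
    boman = boman(seq),
    charge = net_charge(seq, pH = charge_pH),
    hydrophobic_moment = hydrophobic_moment(seq),
    hydrophobicity = hydrophobicity(seq),
    instability = if (length(idx) < 2L) 0 else instability_index(seq),
    isoelectric_point = isoelectric_point(seq),
    mw = molecular_weight(seq),
    mz = mass_over_charge(seq)
  )
  out <- c(fam, scalars)
  stopifnot(length(out) == 96L, all(is.finite(out)))
  out
}

#' Feature vector of an epitope/CDR3beta pair
#'
#' @param epitope,cdr3b Sequences.
#' @param charge_pH pH for the scalar charge feature.
#' @return Named numeric vector of 192 values: the epitope block (names
#'   prefixed `epi_`) followed by the CDR3beta block (prefixed `cdr_`).
#' @export
featurize_pair <- function(epitope, cdr3b, charge_pH = 7) {
  e <- feature_vector(epitope, charge_pH = charge_pH)
  c <- feature_vector(cdr3b, charge_pH = charge_pH)
  stats::setNames(c(e, c),
                  c(paste0("epi_", names(e)), paste0("cdr_", names(c))))
}

#' Featurize a binding dataset
#'
#' Computes the 192-column feature matrix for every record of a binding
#' dataset.  Each distinct sequence is featurized once and cached, so
#' datasets with many TCRs per epitope featurize quickly.
#'
#' @param ds A `binding_dataset` (see [read_binding_dataset()] or
#'   [simulate_binding_data()]).
#' @param charge_pH pH for the scalar charge feature.
#' @return A `feature_matrix`: list with elements `x` (numeric matrix,
#'   n x 192, named columns) and `y` (integer 0/1 label vector).
#' @export
featurize_dataset <- function(ds, charge_pH = 7) {
  stopifnot(inherits(ds, "binding_dataset"))
  .load_scales()
  feat_unique <- function(seqs) {
    u <- unique(seqs)
    m <- t(vapply(u, feature_vector, numeric(96), charge_pH = charge_pH))
    m[match(seqs, u), , drop = FALSE]
  }
  epi <- feat_unique(ds$epitope)
  cdr <- feat_unique(ds$cdr3b)
  colnames(epi) <- paste0("epi_", colnames(epi))
  colnames(cdr) <- paste0("cdr_", colnames(cdr))
  x <- cbind(epi, cdr)
  rownames(x) <- NULL
  structure(list(x = x, y = as.integer(ds$label)), class = "feature_matrix")
}
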