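# Synthetic TCR:epitope datasets with a planted physicochemical binding
# rule.  Because the rule is a function of whole-sequence descriptors (not
# of sequence identity), a correct pipeline generalizes to unseen epitopes
# and TCRs — which is exactly what the hard/strict split evaluations probe.

#' Configuration for the synthetic generator
#'
#' @param n_pairs Number of (CDR3beta, epitope, label) records.
#' @param n_epitopes Size of the epitope pool; epitopes are reused across
#'   pairs, mimicking the many-TCRs-per-epitope structure of curated
#'   binding databases.
#' @param cdr3b_len Inclusive CDR3beta length range (within the curation
#'   filter bounds 9-23).
#' @param epitope_len Inclusive epitope length range (at most 15).
#' @param a_hydro,a_charge,a_mw Coefficients of the planted rule (see
#'   [plant_labels()]).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   latent binding score.
#' @param positive_fraction Fraction of records labelled 1; the label
#'   threshold is the matching quantile of the latent score (0.5 = median,
#'   balanced classes).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pairs = 5000L, n_epitopes = 40L,
                             cdr3b_len = c(9L, 23L),
                             epitope_len = c(8L, 15L),
                             a_hydro = 2, a_charge = 1, a_mw = 0.5,
                             noise_sd = 0.25, positive_fraction = 0.5,
                             seed = 1L) {
  stopifnot(cdr3b_len[1] >= 9L, cdr3b_len[2] <= 23L,
            epitope_len[1] >= 1L, epitope_len[2] <= 15L,
            n_epitopes <= n_pairs, positive_fraction > 0,
            positive_fraction < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_epitopes = as.integer(n_epitopes),
                 cdr3b_len = as.integer(cdr3b_len),
                 epitope_len = as.integer(epitope_len),
                 a_hydro = a_hydro, a_charge = a_charge, a_mw = a_mw,
                 noise_sd = noise_sd,
                 positive_fraction = positive_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.random_seq <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate CDR3beta/epitope sequence pairs
#'
#' Epitopes are drawn with replacement from a pool of `n_epitopes` random
#' sequences (uniform residues, uniform lengths).  CDR3beta sequences carry
#' the canonical C...F motif: they start with C and end with F, with
#' uniform random interior.
#'
#' @param config A `synthetic_config`.
#' @return Data frame with columns `cdr3b` and `epitope`.
#' @export
generate_sequences <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    pool <- unique(.random_seq(config$n_epitopes, config$epitope_len))
    while (length(pool) < config$n_epitopes) {
      pool <- unique(c(pool, .random_seq(1L, config$epitope_len)))
    }
    epitope <- sample(pool, config$n_pairs, replace = TRUE)
    interior <- .random_seq(config$n_pairs, config$cdr3b_len - 2L)
    cdr3b <- paste0("C", interior, "F")
    data.frame(cdr3b = cdr3b, epitope = epitope, stringsAsFactors = FALSE)
  })
}

#' Plant binding labels on sequence pairs
#'
#' The latent binding score of a pair is
#' `s = a_hydro * H(epi) * H(cdr) + a_charge * C(epi) * C(cdr)
#'    + a_mw * MW(cdr) / 1000 + e`,  `e ~ Normal(0, noise_sd)`,
#' where `H` is mean Kyte-Doolittle hydrophobicity, `C` the net charge at
#' pH 7 and `MW` the molecular weight — all descriptor-module quantities.
#' The label is 1 when `s` exceeds the `1 - positive_fraction` quantile of
#' the sample scores, so class balance is set by construction.
#'
#' @param pairs Data frame from [generate_sequences()].
#' @param config The `synthetic_config` used to generate them.
#' @return A `binding_dataset` with the latent scores attached as
#'   `attr(, "latent_score")`.
#' @export
plant_labels <- function(pairs, config) {
  stopifnot(inherits(config, "synthetic_config"),
            all(c("cdr3b", "epitope") %in% names(pairs)))
  desc3 <- function(seqs) {
    u <- unique(seqs)
    m <- t(vapply(u, function(s) {
      c(h = hydrophobicity(s), c = net_charge(s, pH = 7),
        mw = molecular_weight(s))
    }, numeric(3)))
    m[match(seqs, u), , drop = FALSE]
  }
  de <- desc3(pairs$epitope)
  dc <- desc3(pairs$cdr3b)
  noise <- with_seed(config$seed + 1L,
                      stats::rnorm(nrow(pairs), 0, config$noise_sd))
  s <- config$a_hydro * de[, "h"] * dc[, "h"] +
    config$a_charge * de[, "c"] * dc[, "c"] +
    config$a_mw * dc[, "mw"] / 1000 + noise
  cut <- stats::quantile(s, 1 - config$positive_fraction, names = FALSE)
  df <- data.frame(cdr3b = pairs$cdr3b, epitope = pairs$epitope,
                   label = as.integer(s > cut), source = "synthetic",
                   stringsAsFactors = FALSE)
  out <- .new_binding_dataset(df, provenance = list(
    generator = "tcrh synthetic planted-rule",
    config = unclass(config)))
  attr(out, "latent_score") <- s
  out
}

#' Simulate a complete planted-rule binding dataset
#'
#' Convenience wrapper: [generate_sequences()] then [plant_labels()].
#'
#' @param config A `synthetic_config` (default configuration if omitted).
#' @return A `binding_dataset`.
#' @export
#' @examples
#' ds <- simulate_binding_data(synthetic_config(n_pairs = 100, seed = 7))
#' table(ds$label)
simulate_binding_data <- function(config = synthetic_config()) {
  plant_labels(generate_sequences(config), config)
}
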