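# Shared fixtures: random sequences, toy binding tables, small feature sets.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptides <- function(n, len_range = c(8, 15), seed = 1) {
  with_seed(seed, {
    vapply(sample(seq(len_range[1], len_range[2]), n, replace = TRUE),
           function(L) paste(sample(AA20, L, replace = TRUE), collapse = ""),
           character(1))
  })
}

# small binding dataset written to a temp TSV and read back
toy_binding_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_dataset <- function(n = 60, seed = 5, n_epitopes = 6) {
  simulate_binding_data(synthetic_config(
    n_pairs = n, n_epitopes = n_epitopes, seed = seed))
}

# independent per-residue lookup table read straight from the shipped CSV,
# bypassing the package's cached loader
raw_scale_rows <- function() {
  path <- system.file("extdata", "aa_scales.csv", package = "tcrh")
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  rownames(tab) <- tab$scale
  tab
}

# brute-force scale average: explicit per-residue loop over the raw CSV row
brute_scale_average <- function(seq, scale_name, tab = raw_scale_rows()) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (ch in chars) total <- total + tab[scale_name, ch]
  total / length(chars)
}

# deterministic linear score function for SHAP tests
linear_score_fn <- function(w, b = 0) {
  function(x) as.numeric(x %*% w + b)
}
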