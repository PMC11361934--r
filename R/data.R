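# Binding tables: reading, curation filters, and leakage-aware splits.

.new_binding_dataset <- function(df, provenance = list()) {
  rownames(df) <- NULL
  structure(df, class = c("binding_dataset", "data.frame"),
            provenance = provenance)
}

#' Read a CDR3beta/epitope binding table
#'
#' Reads a CSV/TSV with one row per (CDR3beta, epitope, label) observation.
#' Sequences are validated; rows whose sequences contain non-standard
#' residues (or whose label cannot be mapped to 0/1) are dropped and logged.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param cdr3b_col,epitope_col,label_col Column names.
#' @param label_map Optional named vector mapping raw label values to 0/1,
#'   e.g. `c(yes = 1, no = 0)`.  By default labels must already be 0/1.
#' @param sep Field separator override.
#' @return A `binding_dataset`: data frame with columns `cdr3b`, `epitope`,
#'   `label`, `source`, and a `provenance` attribute holding the path and a
#'   log of dropped rows.
#' @export
read_binding_dataset <- function(path, cdr3b_col = "cdr3b",
                                 epitope_col = "epitope",
                                 label_col = "label",
                                 label_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(c(cdr3b_col, epitope_col, label_col), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  clean_seq <- function(x) {
    vapply(x, function(s) tryCatch(validate_sequence(s),
                                   error = function(e) NA_character_),
           character(1), USE.NAMES = FALSE)
  }
  cdr3b <- clean_seq(raw[[cdr3b_col]])
  epitope <- clean_seq(raw[[epitope_col]])
  lab_raw <- raw[[label_col]]
  label <- if (is.null(label_map)) {
    suppressWarnings(as.integer(as.character(lab_raw)))
  } else {
    unname(label_map[as.character(lab_raw)])
  }
  label[!label %in% c(0L, 1L)] <- NA_integer_
  drop_log <- data.frame(
    row = seq_len(n),
    bad_cdr3b = is.na(cdr3b), bad_epitope = is.na(epitope),
    bad_label = is.na(label))
  keep <- !(drop_log$bad_cdr3b | drop_log$bad_epitope | drop_log$bad_label)
  if (!any(keep)) stop("no valid rows in ", path, call. = FALSE)
  df <- data.frame(cdr3b = cdr3b[keep], epitope = epitope[keep],
                   label = as.integer(label[keep]),
                   source = if ("source" %in% names(raw)) {
                     as.character(raw$source[keep])
                   } else {
                     basename(path)
                   },
                   stringsAsFactors = FALSE)
  .new_binding_dataset(df, provenance = list(
    path = path, n_read = n, n_kept = sum(keep),
    dropped = drop_log[!keep, , drop = FALSE]))
}

#' Apply the curation filters
#'
#' Keeps records with CDR3beta length in `cdr3b_len` and epitope length at
#' most `epitope_max_len`; removes exact duplicate (CDR3beta, epitope) pairs
#' keeping the first occurrence; and removes entirely any pair observed with
#' both labels (a label conflict).  Filtering is idempotent.
#'
#' @param ds A `binding_dataset`.
#' @param cdr3b_len Length-2 vector of inclusive CDR3beta length bounds.
#' @param epitope_max_len Maximum epitope length.
#' @return Filtered `binding_dataset`; the per-rule removal counts are in
#'   `attr(, "filter_log")`.
#' @export
apply_filters <- function(ds, cdr3b_len = c(9L, 23L), epitope_max_len = 15L) {
  stopifnot(inherits(ds, "binding_dataset"))
  n0 <- nrow(ds)
  len_ok <- nchar(ds$cdr3b) >= cdr3b_len[1] & nchar(ds$cdr3b) <= cdr3b_len[2] &
    nchar(ds$epitope) <= epitope_max_len
  n_len <- sum(!len_ok)
  df <- ds[len_ok, , drop = FALSE]
  # a pair repeated with the same label is a duplicate (keep first); a pair
  # seen with both labels is a conflict and is removed entirely
  pair <- paste(df$cdr3b, df$epitope, sep = "\r")
  same_dup <- duplicated(paste(pair, df$label, sep = "\r"))
  df <- df[!same_dup, , drop = FALSE]
  n_dup <- sum(same_dup)
  pair <- paste(df$cdr3b, df$epitope, sep = "\r")
  conflict_pairs <- unique(pair[duplicated(pair)])
  in_conflict <- pair %in% conflict_pairs
  n_conflict <- sum(in_conflict)
  df <- df[!in_conflict, , drop = FALSE]
  log <- list(n_input = n0, removed_length = n_len,
              removed_duplicate = n_dup, removed_conflict = n_conflict,
              n_conflict_pairs = length(conflict_pairs), n_output = nrow(df))
  out <- .new_binding_dataset(as.data.frame(df), attr(ds, "provenance"))
  attr(out, "filter_log") <- log
  out
}

.new_split <- function(kind, train_idx, test_idx, seed, test_fraction,
                       discarded_idx = integer(0), report = list()) {
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  structure(list(kind = kind, train_idx = sort(train_idx),
                 test_idx = sort(test_idx),
                 discarded_idx = sort(discarded_idx),
                 seed = seed, test_fraction = test_fraction,
                 report = report),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split:%s> seed=%s  train=%d  test=%d  discarded=%d\n",
              x$kind, format(x$seed), length(x$train_idx),
              length(x$test_idx), length(x$discarded_idx)))
  invisible(x)
}

#' Record-level random train/test split
#'
#' @param ds A `binding_dataset`.
#' @param seed Integer seed; the partition is reproducible given the seed.
#' @param test_fraction Target fraction of records in the test side; the
#'   test size is `max(1, round(test_fraction * n))`.
#' @return A `data_split` of kind `"random"`.
#' @export
random_split <- function(ds, seed, test_fraction = 0.2) {
  stopifnot(inherits(ds, "binding_dataset"), nrow(ds) > 1L)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(ds)
  n_test <- max(1L, round(test_fraction * n))
  test_idx <- with_seed(seed, sample.int(n, n_test))
  .new_split("random", setdiff(seq_len(n), test_idx), test_idx,
             seed, test_fraction)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so seeded helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# greedy seeded assignment of whole groups to the test side until the test
# record count first reaches >= test_fraction * n
.greedy_group_test <- function(groups, seed, test_fraction) {
  n <- length(groups)
  target <- test_fraction * n
  uniq <- unique(groups)
  if (length(uniq) < 2L) {
    stop("need at least 2 distinct group values", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(uniq))
  sizes <- table(groups)[shuffled]
  n_take <- which(cumsum(sizes) >= target)[1]
  if (is.na(n_take)) n_take <- length(shuffled)
  if (n_take == length(shuffled)) {
    # cannot leave the train side empty
    n_take <- length(shuffled) - 1L
    warning("group sizes prevent reaching the target test fraction without ",
            "emptying the train side", call. = FALSE)
  }
  test_groups <- shuffled[seq_len(n_take)]
  biggest <- max(table(groups)) / n
  if (biggest > 1 - test_fraction) {
    warning(sprintf(
      "largest group holds %.0f%% of records; the realized split may be far from the target fraction",
      100 * biggest), call. = FALSE)
  }
  test_groups
}

#' Group-hard train/test split (unseen epitopes or unseen TCRs)
#'
#' Shuffles the distinct values of the grouping key with the seed and
#' greedily assigns whole groups to the test side until the test record
#' count first reaches `test_fraction * n`.  Every record of a group lands
#' on one side, so the test-side key values are disjoint from the train
#' side ("unseen").
#'
#' @param ds A `binding_dataset`.
#' @param group_key `"epitope"` (epitope-hard split) or `"cdr3b"`
#'   (TCR-hard split).
#' @param seed Integer seed.
#' @param test_fraction Target record-level test fraction; the realized
#'   fraction is reported, not forced.
#' @return A `data_split` of kind `"epitope_hard"` or `"tcr_hard"`; the
#'   report lists the number of unseen groups in test and the realized
#'   fraction.
#' @export
group_hard_split <- function(ds, group_key = c("epitope", "cdr3b"), seed,
                             test_fraction = 0.2) {
  stopifnot(inherits(ds, "binding_dataset"))
  group_key <- match.arg(group_key)
  groups <- ds[[group_key]]
  test_groups <- .greedy_group_test(groups, seed, test_fraction)
  test_idx <- which(groups %in% test_groups)
  kind <- if (group_key == "epitope") "epitope_hard" else "tcr_hard"
  .new_split(kind, setdiff(seq_len(nrow(ds)), test_idx), test_idx, seed,
             test_fraction,
             report = list(n_unseen_groups = length(test_groups),
                           realized_test_fraction = length(test_idx) / nrow(ds)))
}

#' Strict train/test split (unseen epitopes AND unseen TCRs)
#'
#' Draws a test-side epitope set and, independently, a test-side CDR3beta
#' set (each by the seeded greedy procedure of [group_hard_split()]).  Test
#' records are those whose epitope and CDR3beta are both test-side; train
#' records are those with both keys train-side; records crossing sides are
#' discarded and counted.  With per-key fraction `g` the realized test
#' fraction is about `g^2` on data with independent keys.
#'
#' @param ds A `binding_dataset`.
#' @param seed Integer seed.
#' @param test_fraction Per-key target fraction handed to the greedy group
#'   assignment of each key.
#' @return A `data_split` of kind `"strict"`, with `discarded_idx` and a
#'   report of the realized fraction and discard count.
#' @export
strict_split <- function(ds, seed, test_fraction = 0.2) {
  stopifnot(inherits(ds, "binding_dataset"))
  test_epi <- .greedy_group_test(ds$epitope, seed, test_fraction)
  test_cdr <- .greedy_group_test(ds$cdr3b, seed + 1L, test_fraction)
  epi_test <- ds$epitope %in% test_epi
  cdr_test <- ds$cdr3b %in% test_cdr
  test_idx <- which(epi_test & cdr_test)
  train_idx <- which(!epi_test & !cdr_test)
  discarded <- which(xor(epi_test, cdr_test))
  if (length(test_idx) == 0L || length(train_idx) == 0L) {
    stop("strict split produced an empty train or test side", call. = FALSE)
  }
  .new_split("strict", train_idx, test_idx, seed, test_fraction,
             discarded_idx = discarded,
             report = list(
               n_test_epitopes = length(test_epi),
               n_test_cdr3b = length(test_cdr),
               n_discarded = length(discarded),
               realized_test_fraction = length(test_idx) / nrow(ds)))
}

#' Subset a binding dataset by split side
#'
#' @param ds A `binding_dataset`.
#' @param split A `data_split`.
#' @param side `"train"` or `"test"`.
#' @return The `binding_dataset` restricted to that side.
#' @export
split_side <- function(ds, split, side = c("train", "test")) {
  side <- match.arg(side)
  idx <- if (side == "train") split$train_idx else split$test_idx
  .new_binding_dataset(as.data.frame(ds[idx, , drop = FALSE]),
                       attr(ds, "provenance"))
}
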