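# Reading, curation filters, and split constructions.

test_that("reading a binding table validates sequences and maps labels", {
  df <- data.frame(cdr3b = c("CASSLGQAYEQYF", "casslpgqgteaff", "CASSX*"),
                   epitope = c("SIINFEKL", "GILGFVFTL", "NLVPMVATV"),
                   label = c("yes", "no", "yes"))
  path <- toy_binding_tsv(df)
  ds <- read_binding_dataset(path, label_map = c(yes = 1, no = 0))
  expect_s3_class(ds, "binding_dataset")
  expect_identical(nrow(ds), 2L)              # bad CDR3b row dropped
  expect_identical(ds$cdr3b[2], "CASSLPGQGTEAFF")  # case normalized
  expect_identical(ds$label, c(1L, 0L))
  prov <- attr(ds, "provenance")
  expect_identical(prov$n_read, 3L)
  expect_true(prov$dropped$bad_cdr3b[1])
})

test_that("reading fails informatively on missing columns or all-bad rows", {
  df <- data.frame(a = "CASSLGF", b = "SIINFEKL", label = 1)
  path <- toy_binding_tsv(df)
  expect_error(read_binding_dataset(path), "missing column")
  expect_error(read_binding_dataset("no/such/file.tsv"), "not found")
  bad <- data.frame(cdr3b = "CASS*", epitope = "SIINFEKL", label = 1)
  expect_error(read_binding_dataset(toy_binding_tsv(bad)), "no valid rows")
})

test_that("curation filters enforce lengths, dedup and conflict removal", {
  df <- data.frame(
    cdr3b = c("CASSLGQA",          # 8 residues: too short
              "CASSLGQAYEQYF",     # kept
              "CASSLGQAYEQYF",     # duplicate pair, same label: dropped
              "CASSPDRGAYEQYF",    # conflict pair, label 1
              "CASSPDRGAYEQYF",    # conflict pair, label 0
              "CASRRPGQGYEQYF"),   # kept
    epitope = c("SIINFEKL", "SIINFEKL", "SIINFEKL", "GILGFVFTL",
                "GILGFVFTL", "AAAWYLWEVHHHHHHH"),  # last: 16-mer epitope
    label = c(1, 1, 1, 1, 0, 1))
  ds <- read_binding_dataset(toy_binding_tsv(df))
  out <- apply_filters(ds)
  expect_identical(nrow(out), 1L)
  expect_identical(out$cdr3b, "CASSLGQAYEQYF")
  log <- attr(out, "filter_log")
  expect_identical(log$removed_length, 2L)     # short CDR3b + long epitope
  expect_identical(log$removed_duplicate, 1L)
  expect_identical(log$removed_conflict, 2L)
  expect_identical(log$n_conflict_pairs, 1L)
  # idempotence (same records; the second pass removes nothing)
  again <- apply_filters(out)
  expect_identical(again$cdr3b, out$cdr3b)
  expect_identical(again$epitope, out$epitope)
  expect_identical(again$label, out$label)
  log2 <- attr(again, "filter_log")
  expect_identical(log2$n_input, log2$n_output)
})

test_that("random split partitions reproducibly at the requested fraction", {
  ds <- toy_dataset(n = 10, seed = 2)
  sp <- random_split(ds, seed = 7, test_fraction = 0.2)
  expect_identical(length(sp$test_idx), 2L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(10))
  expect_identical(random_split(ds, seed = 7)$test_idx, sp$test_idx)
  big <- toy_dataset(n = 1000, seed = 2, n_epitopes = 30)
  expect_false(identical(random_split(big, seed = 1)$test_idx,
                         random_split(big, seed = 2)$test_idx))
  expect_error(random_split(ds, seed = 1, test_fraction = 1.2), "fraction")
})

test_that("group-hard splits keep whole groups on one side", {
  # epitopes E1 x4, E2 x4, E3 x2
  df <- data.frame(
    cdr3b = paste0("CASSLGQAYEQ", c("YF", "AF", "GF", "TF", "VF", "LF",
                                    "IF", "PF", "SF", "RF")),
    epitope = rep(c("SIINFEKLA", "GILGFVFTL", "NLVPMVATV"), c(4, 4, 2)),
    label = rep(c(0, 1), 5))
  ds <- apply_filters(read_binding_dataset(toy_binding_tsv(df)))
  sp <- group_hard_split(ds, "epitope", seed = 3, test_fraction = 0.2)
  test_epis <- unique(ds$epitope[sp$test_idx])
  train_epis <- unique(ds$epitope[sp$train_idx])
  expect_length(intersect(test_epis, train_epis), 0)
  expect_identical(sp$report$n_unseen_groups, length(test_epis))
  expect_identical(sp$kind, "epitope_hard")
  sp2 <- group_hard_split(ds, "cdr3b", seed = 3)
  expect_identical(sp2$kind, "tcr_hard")
  expect_length(intersect(ds$cdr3b[sp2$test_idx], ds$cdr3b[sp2$train_idx]), 0)
})

test_that("hard splits approximate the target fraction on realistic data", {
  ds <- toy_dataset(n = 1000, seed = 21, n_epitopes = 40)
  fracs <- vapply(1:20, function(s) {
    sp <- group_hard_split(ds, "epitope", seed = s, test_fraction = 0.2)
    length(sp$test_idx) / nrow(ds)
  }, numeric(1))
  expect_true(all(abs(fracs - 0.2) <= 0.05))
})

test_that("a dominant group triggers the split-impossible warning", {
  df <- data.frame(cdr3b = paste0("CASSLGQAYEQ",
                                  c("YF", "AF", "GF", "TF", "VF", "LF")),
                   epitope = c(rep("SIINFEKLA", 5), "GILGFVFTL"),
                   label = c(1, 0, 1, 0, 1, 0))
  ds <- apply_filters(read_binding_dataset(toy_binding_tsv(df)))
  expect_warning(group_hard_split(ds, "epitope", seed = 1,
                                  test_fraction = 0.2),
                 "largest group|emptying")
})

test_that("strict split discards crossing records and keeps both keys unseen", {
  ds <- toy_dataset(n = 2000, seed = 8, n_epitopes = 25)
  sp <- strict_split(ds, seed = 4, test_fraction = 0.3)
  expect_length(intersect(ds$epitope[sp$test_idx], ds$epitope[sp$train_idx]),
                0)
  expect_length(intersect(ds$cdr3b[sp$test_idx], ds$cdr3b[sp$train_idx]), 0)
  # conservation: train + test + discarded = n
  expect_identical(length(sp$train_idx) + length(sp$test_idx) +
                     length(sp$discarded_idx), nrow(ds))
  expect_gt(sp$report$n_discarded, 0)
  expect_equal(sp$report$realized_test_fraction,
               length(sp$test_idx) / nrow(ds))
  # split_side round trip
  tr <- split_side(ds, sp, "train")
  expect_identical(nrow(tr), length(sp$train_idx))
})

test_that("split invariants hold across seeds and kinds (property check)", {
  ds <- toy_dataset(n = 500, seed = 31, n_epitopes = 20)
  for (s in 1:10) {
    for (kind in c("random", "epitope_hard", "tcr_hard", "strict")) {
      sp <- switch(kind,
        random = random_split(ds, s),
        epitope_hard = group_hard_split(ds, "epitope", s),
        tcr_hard = group_hard_split(ds, "cdr3b", s),
        strict = strict_split(ds, s))
      expect_length(intersect(sp$train_idx, sp$test_idx), 0)
      expect_identical(length(sp$train_idx) + length(sp$test_idx) +
                         length(sp$discarded_idx), nrow(ds))
      if (kind %in% c("epitope_hard", "strict")) {
        expect_length(intersect(ds$epitope[sp$test_idx],
                                ds$epitope[sp$train_idx]), 0)
      }
      if (kind %in% c("tcr_hard", "strict")) {
        expect_length(intersect(ds$cdr3b[sp$test_idx],
                                ds$cdr3b[sp$train_idx]), 0)
      }
    }
  }
})
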