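# Builds inst/extdata/aa_scales.csv and inst/extdata/diwv.csv, the versioned
# per-residue scale tables bundled with the package.
#
# Provenance classes (recorded per row in the CSV):
#   published          transcribed from the widely reproduced published tables
#   aaindex            extracted from the AAindex database (seqinr) or the
#                      biopython distribution of the published table
#   synthetic_analogue derived here following the family's described
#                      construction recipe (PCA / varimax of real published
#                      per-residue property panels); same dimensionality and
#                      correlation structure as the published family but NOT
#                      the publication's printed values
#
# Run from the package root:  Rscript data-raw/make_scales.R

suppressMessages({
  library(seqinr)
  library(Biostrings)
})

AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]       # entry order below
AA_ALPHA <- sort(AA)                                   # column order in CSV
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

## ---- published tables (rows = scale dims, cols = residues in AA order) ----

# Kidera factors KF1-KF10 (Kidera et al. 1985)
kidera <- t(rbind(
  A = c(-1.56, -1.67, -0.97, -0.27, -0.93, -0.78, -0.20, -0.08,  0.21, -0.48),
  R = c( 0.22,  1.27,  1.37,  1.87, -1.70,  0.46,  0.92, -0.39,  0.23,  0.93),
  N = c( 1.14, -0.07, -0.12,  0.81,  0.18,  0.37, -0.09,  1.23,  1.10, -1.73),
  D = c( 0.58, -0.22, -1.58,  0.81, -0.92,  0.15, -1.52,  0.47,  0.76,  0.70),
  C = c( 0.12, -0.89,  0.45, -1.05, -0.71,  2.41,  1.52, -0.69,  1.13,  1.10),
  Q = c(-0.47,  0.24,  0.07,  1.10,  1.10,  0.59,  0.84, -0.71, -0.03, -2.33),
  E = c(-1.45,  0.19, -1.61,  1.17, -1.31,  0.40,  0.04,  0.38, -0.35, -0.12),
  G = c( 1.46, -1.96, -0.23, -0.16,  0.10, -0.11,  1.32,  2.36, -1.66,  0.46),
  H = c(-0.41,  0.52, -0.28,  0.28,  1.61,  1.01, -1.85,  0.47,  1.13,  1.63),
  I = c(-0.73, -0.16,  1.79, -0.77, -0.54,  0.03, -0.83,  0.51,  0.66, -1.78),
  L = c(-1.04,  0.00, -0.24, -1.10, -0.55, -2.05,  0.96, -0.76,  0.45,  0.93),
  K = c(-0.34,  0.82, -0.23,  1.70,  1.54, -1.62,  1.15, -0.08, -0.48,  0.60),
  M = c(-1.40,  0.18, -0.42, -0.73,  2.00,  1.52,  0.26,  0.11, -1.27,  0.27),
  F = c(-0.21,  0.98, -0.36, -1.43,  0.22, -0.81,  0.67,  1.10,  1.71, -0.44),
  P = c( 2.06, -0.33, -1.15, -0.75,  0.88, -0.45,  0.30, -2.30,  0.74, -0.28),
  S = c( 0.81, -1.08,  0.16,  0.42, -0.21, -0.43, -1.89, -1.15, -0.97, -0.23),
  T = c( 0.26, -0.70,  1.21,  0.63, -0.10,  0.21,  0.24, -1.15, -0.56,  0.19),
  W = c( 0.30,  2.10, -0.72, -1.57, -1.16,  0.57, -0.48, -0.40, -2.30, -0.60),
  Y = c( 1.38,  1.48,  0.80, -0.56,  0.00, -0.68, -0.31,  1.03, -0.05,  0.53),
  V = c(-0.74, -0.71,  2.04, -0.40,  0.50, -0.81, -1.07,  0.06, -0.46,  0.65)))
rownames(kidera) <- paste0("KF", 1:10)

# Z-scales Z1-Z5 (Sandberg et al. 1998)
zscales <- t(rbind(
  A = c( 0.24, -2.32,  0.60, -0.14,  1.30),
  R = c( 3.52,  2.50, -3.50,  1.99, -0.17),
  N = c( 3.05,  1.62,  1.04, -1.15,  1.61),
  D = c( 3.98,  0.93,  1.93, -2.46,  0.75),
  C = c( 0.84, -1.67,  3.71,  0.18, -2.65),
  Q = c( 1.75,  0.50, -1.44, -1.34,  0.66),
  E = c( 3.11,  0.26, -0.11, -3.04, -0.25),
  G = c( 2.05, -4.06,  0.36, -0.82, -0.38),
  H = c( 2.47,  1.95,  0.26,  3.90,  0.09),
  I = c(-3.89, -1.73, -1.71, -0.84,  0.26),
  L = c(-4.28, -1.30, -1.49, -0.72,  0.84),
  K = c( 2.29,  0.89, -2.49,  1.49,  0.31),
  M = c(-2.85, -0.22,  0.47,  1.94, -0.98),
  F = c(-4.22,  1.94,  1.06,  0.54, -0.62),
  P = c(-1.66,  0.27,  1.84,  0.70,  2.00),
  S = c( 2.39, -1.07,  1.15, -1.39,  0.67),
  T = c( 0.75, -2.18, -1.12, -1.46, -0.40),
  W = c(-4.36,  3.94,  0.59,  3.44, -1.59),
  Y = c(-2.54,  2.44,  0.43,  0.04, -1.47),
  V = c(-2.59, -2.64, -1.54, -0.85, -0.02)))
rownames(zscales) <- paste0("Z", 1:5)

# VHSE scales VHSE1-VHSE8 (Mei et al. 2005)
vhse <- t(rbind(
  A = c( 0.15, -1.11, -1.35, -0.92,  0.02, -0.91,  0.36, -0.48),
  R = c(-1.47,  1.45,  1.24,  1.27,  1.55,  1.47,  1.30,  0.83),
  N = c(-0.99,  0.00, -0.37,  0.69, -0.55,  0.85,  0.73, -0.80),
  D = c(-1.15,  0.67, -0.41, -0.01, -2.68,  1.31,  0.03,  0.56),
  C = c( 0.18, -1.67, -0.46, -0.21,  0.00,  1.20, -1.61, -0.19),
  Q = c(-0.96,  0.12,  0.18,  0.16,  0.09,  0.42, -0.20, -0.41),
  E = c(-1.18,  0.40,  0.10,  0.36, -2.16, -0.17,  0.91,  0.02),
  G = c(-0.20, -1.53, -2.63,  2.28, -0.53, -1.18,  2.01, -1.34),
  H = c(-0.43, -0.25,  0.37,  0.19,  0.51,  1.28,  0.93,  0.65),
  I = c( 1.27, -0.14,  0.30, -1.80,  0.30, -1.61, -0.16, -0.13),
  L = c( 1.36,  0.07,  0.26, -0.80,  0.22, -1.37,  0.08, -0.62),
  K = c(-1.17,  0.70,  0.70,  0.80,  1.64,  0.67,  1.63,  0.13),
  M = c( 1.01, -0.53,  0.43,  0.00,  0.23,  0.10, -0.86, -0.68),
  F = c( 1.52,  0.61,  0.96, -0.16,  0.25,  0.28, -1.33, -0.20),
  P = c( 0.22, -0.17, -0.50,  0.05, -0.01, -1.34, -0.19,  3.56),
  S = c(-0.67, -0.86, -1.07, -0.41, -0.32,  0.27, -0.64,  0.11),
  T = c(-0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79,  0.39),
  W = c( 1.50,  2.06,  1.79,  0.75,  0.75, -0.13, -1.01, -0.85),
  Y = c( 0.61,  1.60,  1.17,  0.73,  0.53,  0.25, -0.96, -0.52),
  V = c( 0.76, -0.92, -0.17, -1.91,  0.22, -1.40, -0.24, -0.03)))
rownames(vhse) <- paste0("VHSE", 1:8)

# Cruciani properties PP1-PP3 (Cruciani et al. 2004)
cruciani <- t(rbind(
  A = c(-0.96, -0.76,  0.31),
  R = c( 0.80,  0.63,  0.99),
  N = c( 0.82, -0.57,  0.02),
  D = c( 1.00, -0.89, -1.00),
  C = c(-0.55, -0.47,  0.19),
  Q = c( 0.78, -0.30, -0.38),
  E = c( 0.94, -0.54, -0.99),
  G = c(-0.88, -1.00,  0.49),
  H = c( 0.67, -0.11,  0.37),
  I = c(-0.94, -0.05, -0.18),
  L = c(-0.90,  0.03, -0.24),
  K = c( 0.60,  0.10,  1.00),
  M = c(-0.82,  0.03, -0.08),
  F = c(-0.85,  0.48, -0.58),
  P = c(-0.81, -0.40, -0.07),
  S = c( 0.41, -0.82,  0.57),
  T = c( 0.40, -0.64,  0.37),
  W = c(-0.60,  1.00, -0.48),
  Y = c( 0.31,  0.42, -0.20),
  V = c(-0.90, -0.34, -0.29)))
rownames(cruciani) <- paste0("PP", 1:3)

# MS-WHIM scores (Zaliani & Gancia 1999)
mswhim <- t(rbind(
  A = c(-0.73,  0.20, -0.62),
  R = c(-0.22,  0.27,  1.00),
  N = c( 0.14,  0.20, -0.66),
  D = c( 0.11, -1.00, -0.96),
  C = c(-0.66,  0.26, -0.27),
  Q = c( 0.30,  1.00, -0.30),
  E = c( 0.24, -0.39, -0.04),
  G = c(-0.31, -0.28, -0.75),
  H = c( 0.84,  0.67, -0.78),
  I = c(-0.91,  0.83, -0.25),
  L = c(-0.74,  0.72, -0.16),
  K = c(-0.51,  0.08,  0.60),
  M = c(-0.70,  1.00, -0.32),
  F = c( 0.76,  0.85, -0.34),
  P = c(-0.43,  0.73, -0.60),
  S = c(-0.80,  0.61, -1.00),
  T = c(-0.58,  0.85, -0.89),
  W = c( 1.00,  0.98, -0.47),
  Y = c( 0.97,  0.66, -0.16),
  V = c(-1.00,  0.79, -0.58)))
rownames(mswhim) <- paste0("MSWHIM", 1:3)

# PCP descriptors: five-dimensional MDS embedding of 237 physicochemical
# properties (Venkatarajan & Braun 2001)
pcp <- t(rbind(
  A = c( 0.008,  0.134, -0.475, -0.039,  0.181),
  R = c( 0.171, -0.361,  0.107, -0.258, -0.364),
  N = c( 0.255,  0.038,  0.117,  0.118, -0.055),
  D = c( 0.303, -0.057, -0.014,  0.225,  0.156),
  C = c(-0.132,  0.174,  0.070,  0.565, -0.374),
  Q = c( 0.149, -0.184, -0.030,  0.035, -0.112),
  E = c( 0.221, -0.280, -0.315,  0.157,  0.303),
  G = c( 0.218,  0.562, -0.024,  0.018,  0.106),
  H = c( 0.023, -0.177,  0.041,  0.280, -0.021),
  I = c(-0.353,  0.071, -0.088, -0.195, -0.107),
  L = c(-0.267,  0.018, -0.265, -0.274,  0.206),
  K = c( 0.243, -0.339, -0.044, -0.325, -0.027),
  M = c(-0.239, -0.141, -0.155,  0.321,  0.077),
  F = c(-0.329, -0.023,  0.072, -0.002,  0.208),
  P = c( 0.173,  0.286,  0.407, -0.215,  0.384),
  S = c( 0.199,  0.238, -0.015, -0.068, -0.196),
  T = c( 0.068,  0.147, -0.015, -0.132, -0.274),
  W = c(-0.296, -0.186,  0.389,  0.083,  0.297),
  Y = c(-0.141, -0.057,  0.425, -0.096, -0.091),
  V = c(-0.274,  0.136, -0.187, -0.196, -0.299)))
rownames(pcp) <- paste0("E", 1:5)

# T-scales T1-T5 (Tian et al. 2007, topological descriptors)
tscales <- t(rbind(
  A = c( -9.11, -1.63,  0.63,  1.04,  2.26),
  R = c(  0.23,  3.89, -1.16, -0.39, -0.06),
  N = c( -4.62,  0.66,  1.16, -0.22,  0.93),
  D = c( -4.65,  0.75,  1.39, -0.40,  1.05),
  C = c( -7.35, -0.86, -0.33,  0.80,  0.98),
  Q = c( -3.00,  1.72,  0.28, -0.39,  0.33),
  E = c( -3.03,  1.82,  0.51, -0.58,  0.43),
  G = c(-10.61, -1.21, -0.12,  0.75,  3.25),
  H = c( -1.01, -1.31,  0.01, -1.81, -0.21),
  I = c( -4.25, -0.28, -0.15,  1.40, -0.21),
  L = c( -4.38,  0.28, -0.49,  1.45,  0.02),
  K = c( -2.59,  2.34, -1.69,  0.41, -0.21),
  M = c( -4.08,  0.98, -2.34,  1.64, -0.79),
  F = c(  0.49, -0.94, -0.63, -1.27, -0.44),
  P = c( -5.11, -3.54, -0.53, -0.36, -0.29),
  S = c( -7.44, -0.65,  0.68, -0.17,  1.58),
  T = c( -5.97, -0.62,  1.11,  0.31,  0.95),
  W = c(  5.73, -2.67, -0.07, -1.96, -0.54),
  Y = c(  2.08, -0.47, -0.07, -1.67, -0.35),
  V = c( -5.87, -0.94,  0.28,  1.10,  0.48)))
rownames(tscales) <- paste0("T", 1:5)

# Boman per-residue solubility contribution (negated Radzicka-Wolfenden
# transfer free energies; the whole-sequence Boman index is their mean).
# Proline was not measured in the original work; set to 0 by convention.
boman <- matrix(c(-1.81, 14.92, 6.64, 8.72, -1.28, 5.54, 6.81, -0.94, 4.66,
                  -4.92, -4.92, 5.55, -2.35, -2.98, 0.00, 3.40, 2.57, -2.33,
                  0.14, -4.04), nrow = 1, dimnames = list("boman", AA))

# Average residue masses (Da); water 18.01524, proton 1.00728 live in R code.
mass <- matrix(c(71.0788, 156.1875, 114.1038, 115.0886, 103.1388, 128.1307,
                 129.1155, 57.0519, 137.1411, 113.1594, 113.1594, 128.1741,
                 131.1926, 147.1766, 97.1167, 87.0782, 101.1051, 186.2132,
                 163.1760, 99.1326), nrow = 1,
               dimnames = list("average_mass", AA))

## ---- AAindex-sourced tables -----------------------------------------------

data(aaindex, package = "seqinr")
aaidx <- function(id) {
  v <- aaindex[[id]]$I
  out <- v[AA3[AA]]
  names(out) <- AA
  out
}
sneath <- rbind(SV1 = aaidx("SNEP660101"), SV2 = aaidx("SNEP660102"),
                SV3 = aaidx("SNEP660103"), SV4 = aaidx("SNEP660104"))
eisenberg <- matrix(aaidx("EISD840101"), nrow = 1,
                    dimnames = list("eisenberg", AA))
kyte_doolittle <- matrix(aaidx("KYTJ820101"), nrow = 1,
                         dimnames = list("kyte_doolittle", AA))

## ---- derived analogue families --------------------------------------------

set.seed(20240816)  # fixed; derivation is deterministic anyway

# residue x index matrix of all complete AAindex entries
complete <- Filter(function(x) !any(is.na(x$I)), aaindex)
panelmat <- sapply(complete, function(x) { v <- x$I[AA3[AA]]; names(v) <- AA; v })
rownames(panelmat) <- AA
descs <- tolower(sapply(complete, function(x) x$D))

pca_family <- function(keyword_regex, k, prefix) {
  cols <- if (is.null(keyword_regex)) seq_len(ncol(panelmat)) else
    grep(keyword_regex, descs)
  X <- panelmat[, cols, drop = FALSE]
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  sc <- p$x[, seq_len(k), drop = FALSE]
  sc <- vapply(seq_len(ncol(sc)), function(j) {
    v <- sc[, j]
    v <- (v - mean(v)) / sd(v)
    if (v[which.max(abs(v))] < 0) -v else v   # deterministic sign
  }, numeric(nrow(sc)))
  rownames(sc) <- AA
  t(`colnames<-`(sc, paste0(prefix, seq_len(k))))
}

fasgai  <- pca_family("hydrophob|turn|helix|bulk|composition|flexib|electron",
                      6, "F")
protfp  <- pca_family(NULL, 8, "ProtFP")
stscale <- pca_family("hydrophob|steric|electron|topolog|volume|polar",
                      8, "ST")
svger   <- pca_family("volume|size|shape|steric|buried|accessib", 11, "SVGER")
# Physical descriptors: PD1 volume-related, PD2 hydrophilicity-related
pd1 <- pca_family("volume|bulk", 1, "PDVOL")
pd2 <- pca_family("hydrophil|hydrophob", 1, "PDHYD")
physical <- rbind(PD1 = pd1[1, ], PD2 = -pd2[1, ])  # PD2: hydrophilic positive
# BLOSUM indices: varimax-rotated principal decomposition of BLOSUM62
data(BLOSUM62, package = "Biostrings")
B <- BLOSUM62[AA, AA]
pb <- prcomp(scale(B))
vm <- varimax(pb$x[, 1:10], normalize = FALSE)
bl <- pb$x[, 1:10] %*% vm$rotmat
bl <- apply(bl, 2, function(v) {
  v <- (v - mean(v)) / sd(v)
  if (v[which.max(abs(v))] < 0) -v else v
})
rownames(bl) <- AA
blosum <- t(`colnames<-`(bl, paste0("BLOSUM", 1:10)))

## ---- assemble and write ----------------------------------------------------

fam <- function(family, m, provenance)
  data.frame(family = family, scale = rownames(m), provenance = provenance,
             round(m[, AA_ALPHA, drop = FALSE], 6), check.names = FALSE)

tab <- rbind(
  fam("blosum_indices", blosum, "synthetic_analogue"),
  fam("cruciani",       cruciani, "published"),
  fam("fasgai",         fasgai, "synthetic_analogue"),
  fam("kidera",         kidera, "published"),
  fam("mswhim",         mswhim, "published"),
  fam("pcp",            pcp, "published"),
  fam("physical",       physical, "synthetic_analogue"),
  fam("protfp",         protfp, "synthetic_analogue"),
  fam("sneath",         sneath, "aaindex"),
  fam("svger",          svger, "synthetic_analogue"),
  fam("st_scales",      stscale, "synthetic_analogue"),
  fam("t_scales",       tscales, "published"),
  fam("vhse",           vhse, "published"),
  fam("z_scales",       zscales, "published"),
  fam("boman",          boman, "published"),
  fam("hydrophobicity", kyte_doolittle, "aaindex"),
  fam("hydrophobicity", eisenberg, "aaindex"),
  fam("mass",           mass, "published")
)

header <- c(
  "# aa_scales.csv -- per-residue amino-acid scale tables, version 1",
  "# One row per scale dimension; columns are the 20 standard residues.",
  "# provenance: published = transcribed from the original publication;",
  "#   aaindex = extracted from AAindex (seqinr) / biopython distributions;",
  "#   synthetic_analogue = derived in data-raw/make_scales.R by PCA/varimax",
  "#   of real published property panels following the family's construction",
  "#   recipe; NOT the publication's printed values (see package vignette).",
  "# Families: blosum_indices (BLOSUM62 varimax decomposition, cf. Georgiev",
  "#   2009), cruciani (Cruciani 2004), fasgai (cf. Liang & Li 2007), kidera",
  "#   (Kidera 1985), mswhim (Zaliani & Gancia 1999), pcp (Venkatarajan &",
  "#   Braun 2001), physical (cf. Barley 2018), protfp (cf. van Westen 2013),",
  "#   sneath (Sneath 1966, AAindex SNEP6601xx), svger (cf. Tong 2008),",
  "#   st_scales (cf. Yang 2010), t_scales (Tian 2007), vhse (Mei 2005),",
  "#   z_scales (Sandberg 1998), boman (Boman 2003 / Radzicka-Wolfenden),",
  "#   hydrophobicity (Kyte-Doolittle KYTJ820101; Eisenberg EISD840101),",
  "#   mass (IUPAC average residue masses)."
)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
body <- capture.output(write.csv(tab, row.names = FALSE))
writeLines(c(header, body), "inst/extdata/aa_scales.csv")

# DIWV dipeptide instability weights (Guruprasad 1990), via biopython
diwv_json <- system2("python", c("-c", shQuote(
  "import json; from Bio.SeqUtils.ProtParamData import DIWV; print(json.dumps(DIWV))")),
  stdout = TRUE)
diwv <- jsonlite::fromJSON(paste(diwv_json, collapse = ""))
dm <- matrix(0, 20, 20, dimnames = list(AA_ALPHA, AA_ALPHA))
for (a in AA_ALPHA) for (b in AA_ALPHA) dm[a, b] <- diwv[[a]][[b]]
diwv_header <- c(
  "# diwv.csv -- Guruprasad (1990) dipeptide instability weight values,",
  "# version 1. Rows: first residue of the dipeptide; columns: second.",
  "# Extracted from the biopython distribution of the published table.")
body <- capture.output(write.csv(
  data.frame(first = AA_ALPHA, dm, check.names = FALSE), row.names = FALSE))
writeLines(c(diwv_header, body), "inst/extdata/diwv.csv")

# checksums of the data lines (non-comment), pasted into R/scales.R
datasum <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tf <- tempfile(); writeLines(lines, tf)
  unname(tools::md5sum(tf))
}
cat("aa_scales md5:", datasum("inst/extdata/aa_scales.csv"), "\n")
cat("diwv md5:     ", datasum("inst/extdata/diwv.csv"), "\n")
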