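# Bundled per-residue scale tables and related physical constants.

#' @keywords internal
"_PACKAGE"

# The 20 standard one-letter amino-acid codes, alphabetical.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Canonical family order of the 88 family descriptor dimensions.
FAMILY_ORDER <- c("blosum_indices", "cruciani", "fasgai", "kidera", "mswhim",
                  "pcp", "physical", "protfp", "sneath", "svger", "st_scales",
                  "t_scales", "vhse", "z_scales")

# md5 checksums of the data lines (comment header excluded) of the shipped
# CSVs; verified on first load.
.SCALES_MD5 <- c(aa_scales = "0147eced578a74b73e996148f9d0d3e9",
                 diwv      = "faf13a6cadd562d2060f46095762420f")

AVG_WATER_MASS <- 18.01524   # Da, average
PROTON_MASS    <- 1.00728    # Da

.tcrh <- new.env(parent = emptyenv())

.data_md5 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf)
  unname(tools::md5sum(tf))
}

.load_scales <- function() {
  if (!is.null(.tcrh$scales)) {
    return(invisible(NULL))
  }
  path <- system.file("extdata", "aa_scales.csv", package = "tcrh",
                      mustWork = TRUE)
  if (.data_md5(path) != .SCALES_MD5[["aa_scales"]]) {
    warning("aa_scales.csv does not match its recorded checksum; ",
            "the bundled scale tables may have been modified", call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  stopifnot(all(AA_ALPHABET %in% names(tab)))
  m <- as.matrix(tab[, AA_ALPHABET])
  rownames(m) <- tab$scale
  fam_rows <- tab$family %in% FAMILY_ORDER
  fam_tab <- tab[fam_rows, ]
  # 20 x 88 matrix in canonical family order, for fast block featurization
  ord <- order(match(fam_tab$family, FAMILY_ORDER))
  fam_tab <- fam_tab[ord, ]
  S <- t(m[fam_tab$scale, , drop = FALSE])
  .tcrh$scales <- list(
    all = m,
    family_of = stats::setNames(tab$family, tab$scale),
    provenance = stats::setNames(tab$provenance, tab$scale),
    families = split(fam_tab$scale, fam_tab$family)[FAMILY_ORDER],
    family_matrix = S,
    boman = m["boman", ],
    mass = m["average_mass", ],
    hydro = list(kyte_doolittle = m["kyte_doolittle", ],
                 eisenberg = m["eisenberg", ])
  )
  dpath <- system.file("extdata", "diwv.csv", package = "tcrh",
                       mustWork = TRUE)
  if (.data_md5(dpath) != .SCALES_MD5[["diwv"]]) {
    warning("diwv.csv does not match its recorded checksum", call. = FALSE)
  }
  dtab <- utils::read.csv(dpath, comment.char = "#", check.names = FALSE)
  dm <- as.matrix(dtab[, AA_ALPHABET])
  rownames(dm) <- dtab$first
  .tcrh$diwv <- dm[AA_ALPHABET, AA_ALPHABET]
  invisible(NULL)
}

#' List the bundled descriptor scale families
#'
#' @return Named list: for each of the 14 descriptor families, the character
#'   vector of its scale-dimension names (88 dimensions in total), in the
#'   canonical order used by [feature_vector()].
#' @export
#' @examples
#' lengths(aa_scale_families())
aa_scale_families <- function() {
  .load_scales()
  .tcrh$scales$families
}

#' Look up one bundled per-residue scale table
#'
#' A scale table maps each of the 20 standard amino acids to one real number
#' (e.g. Kidera factor 4, or the Kyte-Doolittle hydropathy value).
#'
#' @param name Scale-dimension name, e.g. `"KF4"`, `"Z1"`, `"boman"`,
#'   `"kyte_doolittle"`.
#' @return Named numeric vector of length 20 (names are residues), with
#'   attributes `scale` (the name), `family` and `provenance`.
#' @export
#' @examples
#' scale_table("KF1")[["A"]]
scale_table <- function(name) {
  .load_scales()
  m <- .tcrh$scales$all
  if (!name %in% rownames(m)) {
    stop("unknown scale table: ", name, call. = FALSE)
  }
  structure(m[name, ], scale = name,
            family = unname(.tcrh$scales$family_of[name]),
            provenance = unname(.tcrh$scales$provenance[name]))
}

#' Guruprasad dipeptide instability weights
#'
#' @return 20 x 20 numeric matrix; rows index the first residue of a
#'   dipeptide, columns the second.
#' @export
diwv_table <- function() {
  .load_scales()
  .tcrh$diwv
}

# Bundled acid-dissociation constant sets (N-/C-terminus and ionizable side
# chains), used by net_charge() and isoelectric_point().
.PKA_SETS <- list(
  emboss = c(nterm = 8.6, cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

#' Acid-dissociation (pKa) constant sets
#'
#' @param source Name of the bundled set; currently `"emboss"`.
#' @return Named numeric vector with elements `nterm`, `cterm`, `K`, `R`,
#'   `H`, `D`, `E`, `C`, `Y`, carrying a `source` attribute.
#' @export
#' @examples
#' pka_set()[["nterm"]]
pka_set <- function(source = "emboss") {
  if (!source %in% names(.PKA_SETS)) {
    stop("unknown pKa set: ", source, call. = FALSE)
  }
  pk <- .PKA_SETS[[source]]
  stopifnot(all(pk > 0 & pk < 14))
  structure(pk, source = source)
}

#' Average residue masses
#'
#' @return Named numeric vector of the 20 average residue (amino acid minus
#'   water) masses in daltons.
#' @export
residue_masses <- function() {
  .load_scales()
  .tcrh$scales$mass
}
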