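#' @useDynLib graphgo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm setNames
#' @importFrom utils head read.table write.table
NULL

# Derive a child seed from a parent seed and a label, staying inside the
# 32-bit signed range R's set.seed() accepts.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

# Evaluate an expression with a locally-scoped RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_graphgo <- function(..., class = "graphgo_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical amino-acid alphabet: the 20 standard residues in alphabetical
# one-letter order, then 'X' for anything nonstandard.
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # common nonstandard residues collapse to their parent where unambiguous
  MSE = "M", SEC = "U", PYL = "O"
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

aa_three_to_one <- function(three) {
  one <- unname(AA_THREE_TO_ONE[toupper(three)])
  one[is.na(one) | !(one %in% AA_ALPHABET)] <- "X"
  one
}
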