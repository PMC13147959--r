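# Internal helpers shared across modules.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3_TO_1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y", UNK = "X", MSE = "M"
)

AA1_TO_3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR", X = "UNK"
)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

#' Derive a reproducible child seed from a master seed and a key
#'
#' A small stable string hash (FNV-1a over the UTF-8 bytes of the key, folded
#' with the master seed) used to give every replicate of a generated dataset
#' its own deterministic RNG stream without storing per-replicate seeds.
#' The result is a non-negative integer below 2^31.
#'
#' @param master_seed integer master seed.
#' @param ... key components (coerced to character and joined with "/").
#' @return a single integer in [0, 2^31 - 1].
#' @keywords internal
derive_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), function(x) paste0(format(x, digits = 15),
                                                    collapse = ","),
                      character(1)), collapse = "/")
  bytes <- utf8ToInt(key)
  # FNV-1a in double arithmetic; all intermediates stay below 2^53 exact range
  h <- (as.numeric(master_seed) %% 2147483647) + 2166136261
  for (b in bytes) {
    h <- (h %% 16777216) * 127 + b  # fold to keep exact, mix multiplicatively
    h <- (h * 31 + 17) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
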