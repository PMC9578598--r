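# Internal helpers: alphabets, codon usage, seeded RNG scope, string utilities.

# IUPAC nucleotide codes -> the set of concrete bases each matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Most-used human codon per amino acid; fixed so back-translation is
# deterministic and planted repeats are nucleotide-perfect.
HUMAN_CODON <- c(
  A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG", `*` = "TGA"
)

# Kyte-Doolittle hydropathy scale.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

collapse0 <- function(x) paste0(x, collapse = "")

randomDna <- function(n) collapse0(sample(c("A", "C", "G", "T"), n, replace = TRUE))

randomProtein <- function(n) {
  collapse0(sample(names(KYTE_DOOLITTLE), n, replace = TRUE))
}

backTranslate <- function(protein) {
  aa <- chars(toupper(protein))
  bad <- setdiff(aa, names(HUMAN_CODON))
  if (length(bad))
    stop("cannot back-translate residue(s): ", paste(unique(bad), collapse = ", "))
  collapse0(HUMAN_CODON[aa])
}

# All substrings of length k, at every start offset (vectorised).
kmersOf <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

asSeqChar <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x)) stop("expected a character or XString sequence")
  toupper(x)
}

stopifnotScalarSeq <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) stop(what, " must be a single non-empty string")
  invisible(x)
}
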