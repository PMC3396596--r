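# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps all package randomness explicit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit hash of a string, used to derive per-record seeds so
# that results do not depend on record order.
string_seed <- function(x, base_seed = 0L) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + as.numeric(base_seed)) %% 2147483647)
}

# Split a protein/nucleotide string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map residues to 0-based indices in AA_ALPHABET; unknowns (X etc.) -> -1.
aa_index0 <- function(chars) {
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- 0L
  idx - 1L
}

# Canonical key for a bipartition side (set of leaf labels).
bipart_key <- function(leaves) paste(sort(leaves), collapse = "\r")

# Format a branch length with 6 decimals (the on-disk Newick contract).
fmt_brlen <- function(x) sprintf("%.6f", x)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
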