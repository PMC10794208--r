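#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit hash of a string; used to derive per-contig RNG
# streams so augmentation is independent of contig order.
str_hash31 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a valid 32-bit seed from a base seed and a stream label.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 1000003 + str_hash31(as.character(label))) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

cb_log <- function(stage, ...) {
  message(sprintf("[contrabin:%s] %s", stage, sprintf(...)))
}

#' Assembly N50
#'
#' Length `L` such that contigs of length at least `L` together contain at
#' least half of the total assembly length.
#'
#' @param lengths Integer vector of contig lengths in bp.
#' @return N50 in bp (0 for an empty input).
#' @examples
#' n50(c(2000, 2000, 1000))  # 2000
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) return(0L)
  ls <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(ls[which(cumsum(ls) >= sum(ls) / 2)[1]])
}
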