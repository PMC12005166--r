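# Internal helpers shared across modules.

# Deterministic seed streams. One master seed expands to per-(point, region,
# replicate) seeds without touching R's global RNG. All values stay inside
# [1, 2^31 - 2] so they are valid 32-bit seeds everywhere (R, msprime, C++).
derive_seeds <- function(master_seed, n, stream = 0L) {
  m <- 2147483629 # large prime < 2^31
  s0 <- (as.numeric(master_seed) + 999983 * as.numeric(stream)) %% m
  k <- seq_len(n)
  # affine step: products stay < 2^53 so doubles are exact
  ((s0 * 48271 + k * 16807) %% m) + 1
}

# Stable numeric seed from a character key (used to give each grid point its
# own reproducible simulation stream independent of evaluation order).
key_seed <- function(key, master_seed) {
  bytes <- utf8ToInt(key)
  m <- 2147483629
  h <- as.numeric(master_seed) %% m
  for (b in bytes) h <- (h * 131 + b) %% m
  h + 1
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Interval utilities on 0-based half-open tibbles with columns start, end.
# Backed by IRanges (shifted to 1-based closed internally).
iv_to_ir <- function(iv) {
  IRanges::IRanges(start = iv$start + 1, end = iv$end)
}

ir_to_iv <- function(ir) {
  tibble(start = BiocGenerics::start(ir) - 1, end = BiocGenerics::end(ir))
}

iv_normalize <- function(iv) {
  if (nrow(iv) == 0) return(tibble(start = numeric(), end = numeric()))
  ir_to_iv(IRanges::reduce(iv_to_ir(iv)))
}

iv_union_bp <- function(iv) {
  sum(iv_normalize(iv)$end - iv_normalize(iv)$start)
}

iv_complement <- function(iv, lower, upper) {
  ir <- IRanges::gaps(IRanges::reduce(iv_to_ir(iv)),
                      start = lower + 1, end = upper)
  out <- ir_to_iv(ir)
  if (nrow(iv) == 0) out <- tibble(start = lower, end = upper)
  out[out$end > out$start, , drop = FALSE]
}

iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(start = numeric(), end = numeric()))
  ir_to_iv(IRanges::intersect(IRanges::reduce(iv_to_ir(a)),
                              IRanges::reduce(iv_to_ir(b))))
}

iv_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(tibble(start = numeric(), end = numeric()))
  if (nrow(b) == 0) return(iv_normalize(a))
  ir_to_iv(IRanges::setdiff(IRanges::reduce(iv_to_ir(a)),
                            IRanges::reduce(iv_to_ir(b))))
}

# Membership of (0-based) positions in 0-based half-open intervals.
pos_in_intervals <- function(pos, iv) {
  if (length(pos) == 0) return(logical(0))
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  ir <- IRanges::reduce(iv_to_ir(iv))
  q <- IRanges::IRanges(start = floor(pos) + 1, width = 1)
  IRanges::overlapsAny(q, ir)
}

# Run code under a local RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

python_bin <- function() {
  bin <- Sys.getenv("POPBASELINE_PYTHON", unset = Sys.which("python"))
  if (!nzchar(bin)) abort("No `python` interpreter found on PATH.")
  bin
}
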