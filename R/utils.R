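# Shared helpers: reproducible seeding and small validators.

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed, a stage label and a replicate index
#' to a new 32-bit seed. Every stochastic step in the package draws its seed
#' through this splitter so that a whole study is reproducible from a single
#' master seed without correlating random streams across stages.
#'
#' @param master Integer master seed.
#' @param stage Single string naming the stage (e.g. `"pa"`, `"perm"`).
#' @param index Replicate index within the stage (default 0).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' child_seed(42, "permutation", 3)
child_seed <- function(master, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(master) %% 2147483629 * 7919 +
                h * 104729 + as.numeric(index) * 7907) %% 2147483629)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

#' Shannon evenness of composition fractions
#'
#' Evenness of a composition vector (e.g. landcover fractions in one cell):
#' Shannon entropy of the renormalised fractions divided by `log(k)`, so 1
#' means all classes equally represented and 0 means a single class.
#'
#' @param p Non-negative fractions (need not sum to one; renormalised).
#' @return Evenness in `[0, 1]`; `NA` if all fractions are zero.
#' @export
shannon_evenness <- function(p) {
  p <- p[!is.na(p)]
  if (any(p < 0)) stop("fractions must be non-negative")
  s <- sum(p)
  if (s <= 0) return(NA_real_)
  p <- p / s
  p <- p[p > 0]
  if (length(p) == 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}
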