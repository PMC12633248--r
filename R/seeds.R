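#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus an arbitrary set of string/numeric
#' tags (stage name, subject id, replicate index, ...) to a 31-bit integer
#' seed. Subject-level results are thereby reproducible independently of the
#' order in which subjects are processed.
#'
#' @param master Integer master seed.
#' @param ... Tags identifying the consumer (coerced to character).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(1, "simulate", "sub-001")
#' @export
child_seed <- function(master, ...) {
  tags <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                       character(1)), collapse = "/")
  bytes <- c(utf8ToInt(tags), 0L)
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1, in double precision
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
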