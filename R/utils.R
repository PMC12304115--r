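#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of their inputs and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Jaccard similarity of two species assemblages
#'
#' `|A intersect B| / |A union B|`; two empty assemblages are defined as
#' identical (similarity 1).
#'
#' @param set_a,set_b vectors of species identifiers.
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}
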