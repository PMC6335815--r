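#' Expected inbreeding coefficient under repeated full-sib mating
#'
#' Iterates the classical recurrence for single-pair full-sibling
#' mating, `F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4`, starting from a
#' non-inbred base population (`F_0 = F_{-1} = 0`). Used to check the
#' expected homozygosity of inbred laboratory strains; after 17
#' generations the expectation exceeds 0.7 (it is ~0.974).
#'
#' @param generations number of generations of full-sib mating (>= 1).
#' @return expected inbreeding coefficient F in `[0, 1)`.
#' @examples
#' fullsib_inbreeding_coefficient(1)   # 0.25
#' fullsib_inbreeding_coefficient(17)  # > 0.7
#' @export
fullsib_inbreeding_coefficient <- function(generations) {
  if (!is.numeric(generations) || length(generations) != 1L ||
      is.na(generations) || generations < 1 ||
      generations != floor(generations)) {
    stop("'generations' must be a single integer >= 1")
  }
  f_prev2 <- 0; f_prev1 <- 0
  for (t in seq_len(generations)) {
    f <- (1 + 2 * f_prev1 + f_prev2) / 4
    f_prev2 <- f_prev1
    f_prev1 <- f
  }
  f_prev1
}
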