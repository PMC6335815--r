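#' Tabulate per-branch evolutionary events
#'
#' Builds the per-branch event table underlying the rate analysis:
#' orthogroups arising on each branch (via their origin branch),
#' inparalogues and distinct inparalogue-generating orthogroups on
#' each terminal branch, and positively selected genes on every
#' branch, together with the silent-site branch lengths.
#'
#' @param orthology an `orthology_map` (from [classify_orthology()] or
#'   [orthology_from_truth()]).
#' @param selection_flags data.frame (gene_id, branch, selected) with
#'   selected in \{0, 1\}; `branch` must name branches of the tree.
#' @param tree species tree carrying silent branch lengths.
#' @param lengths optional named vector of silent branch lengths
#'   overriding the tree's edge lengths.
#' @return data.frame, one row per branch: branch, silent_length,
#'   terminal, n_orthogroups_arising (NA on terminal branches),
#'   n_og_inparalogues, n_inparalogues (NA on internal branches),
#'   n_selected.
#' @export
tabulate_branch_events <- function(orthology, selection_flags, tree,
                                   lengths = NULL) {
  bt <- branch_table(ensure_node_labels(tree))
  L <- setNames(bt$length, bt$branch)
  if (!is.null(lengths)) L[names(lengths)] <- lengths
  known <- c(bt$branch, "root")
  if (nrow(selection_flags)) {
    bad <- setdiff(unique(selection_flags$branch), known)
    if (length(bad)) stop("selection flag on unknown branch: ",
                          paste(bad, collapse = ", "))
  }
  pg <- orthology$genes
  og <- orthology$orthogroups
  arising <- table(og$origin_branch)
  inp <- pg[pg$category == "inparalogue", , drop = FALSE]
  n_inp <- table(inp$species)
  n_og_inp <- tapply(inp$orthogroup_id, inp$species,
                     function(x) length(unique(x[!is.na(x)])))
  sel <- selection_flags[selection_flags$selected == 1, , drop = FALSE]
  n_sel <- table(sel$branch)
  gv <- function(tab, key) if (key %in% names(tab)) as.integer(tab[[key]]) else 0L
  out <- data.frame(
    branch = bt$branch,
    silent_length = unname(L[bt$branch]),
    terminal = bt$terminal,
    n_orthogroups_arising = ifelse(bt$terminal, NA_integer_,
                                   vapply(bt$branch, function(b)
                                     gv(arising, b), 0L)),
    n_og_inparalogues = ifelse(bt$terminal,
                               vapply(bt$branch, function(b)
                                 gv(n_og_inp, b), 0L), NA_integer_),
    n_inparalogues = ifelse(bt$terminal,
                            vapply(bt$branch, function(b)
                              gv(n_inp, b), 0L), NA_integer_),
    n_selected = vapply(bt$branch, function(b) gv(n_sel, b), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expected counts and excesses under a length-proportional rate
#'
#' For one event class with counts `c_i` on branches of silent length
#' `L_i`, the expected count under a single global rate is
#' `E_i = L_i * sum(c) / sum(L)` and the excess is `c_i - E_i` (so the
#' excesses sum to zero by construction). "Disproportionate" is
#' formalised as the Poisson tail probabilities `P(X >= c_i)` (upper)
#' and `P(X <= c_i)` (lower) at mean `E_i`; the published analysis only
#' inspects the plots, so the tail test is an addition of this
#' implementation.
#'
#' @param counts non-negative integer counts (NA rows are dropped).
#' @param lengths silent branch lengths, same length as `counts`.
#' @return data.frame (count, length, expected, excess, p_upper,
#'   p_lower) aligned with the non-NA input rows; names kept.
#' @export
expected_and_excess <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("length mismatch")
  keep <- !is.na(counts)
  counts <- counts[keep]; lengths <- lengths[keep]
  if (sum(lengths) <= 0) stop("total silent length must be positive")
  rate <- sum(counts) / sum(lengths)
  expected <- lengths * rate
  excess <- counts - expected
  data.frame(count = counts, length = lengths, expected = expected,
             excess = excess,
             p_upper = ppois(counts - 1, expected, lower.tail = FALSE),
             p_lower = ppois(counts, expected),
             row.names = names(counts))
}

#' Augment a branch-event table with expected counts and excesses
#'
#' Applies [expected_and_excess()] to each event class of a
#' [tabulate_branch_events()] table (orthogroup originations over the
#' internal branches; inparalogues, inparalogue-generating orthogroups
#' and selected genes over the branches where they are defined).
#'
#' @param table output of [tabulate_branch_events()].
#' @return the table with `expected_*` and `excess_*` columns added.
#' @export
branch_event_excess <- function(table) {
  for (cls in c("n_orthogroups_arising", "n_og_inparalogues",
                "n_inparalogues", "n_selected")) {
    ee <- expected_and_excess(setNames(table[[cls]], table$branch),
                              table$silent_length)
    table[[sub("^n_", "expected_", cls)]] <- NA_real_
    table[[sub("^n_", "excess_", cls)]] <- NA_real_
    m <- match(rownames(ee), table$branch)
    table[[sub("^n_", "expected_", cls)]][m] <- ee$expected
    table[[sub("^n_", "excess_", cls)]][m] <- ee$excess
  }
  table
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the exact binomial tails: the lower bound solves the upper
#' binomial tail equal to `(1 - conf) / 2` (0 when `x = 0`) and the
#' upper bound the lower tail (1 when `x = n`); computed via the beta
#' quantile identity.
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (>= 1).
#' @param conf confidence level, default 0.95.
#' @return numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' round(100 * clopper_pearson(95, 1237), 2)  # 6.26 9.31
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n || x != floor(x) || n != floor(n)) {
    stop("need integers 0 <= x <= n, n >= 1")
  }
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Duplication-selection association table
#'
#' For each species, compares the proportion of positively selected
#' genes among genes lacking inparalogues with the proportion among
#' genes that generated inparalogues: percentages (two decimals,
#' round-half-even), exact Clopper-Pearson 95% intervals, and a
#' two-sided Fisher exact test on the 2x2 table.
#'
#' @param flags data.frame with columns species, has_inparalogue
#'   (logical), is_selected (logical), one row per gene.
#' @param conf confidence level for the intervals.
#' @return data.frame, one row per species: x/n, pct and CI for both
#'   strata, and `p_fisher`. Strata with `n = 0` get `NA` percentages.
#' @export
association_table <- function(flags, conf = 0.95) {
  stopifnot(all(c("species", "has_inparalogue", "is_selected") %in%
                names(flags)))
  out <- lapply(split(flags, flags$species), function(d) {
    no <- d[!d$has_inparalogue, ]; yes <- d[d$has_inparalogue, ]
    row <- data.frame(species = d$species[1],
                      x_noInp = sum(no$is_selected), n_noInp = nrow(no),
                      x_inp = sum(yes$is_selected), n_inp = nrow(yes))
    fill <- function(x, n) {
      if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
      ci <- clopper_pearson(x, n, conf)
      c(round(100 * x / n, 2), round(100 * ci[[1]], 2),
        round(100 * ci[[2]], 2))
    }
    a <- fill(row$x_noInp, row$n_noInp)
    b <- fill(row$x_inp, row$n_inp)
    row$pct_noInp <- a[1]; row$ci_lo_noInp <- a[2]; row$ci_hi_noInp <- a[3]
    row$pct_inp <- b[1]; row$ci_lo_inp <- b[2]; row$ci_hi_inp <- b[3]
    row$p_fisher <- if (row$n_noInp > 0 && row$n_inp > 0) {
      m <- matrix(c(row$x_inp, row$n_inp - row$x_inp,
                    row$x_noInp, row$n_noInp - row$x_noInp), 2, 2)
      fisher.test(m)$p.value
    } else NA_real_
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared-response excess over an independence null
#'
#' Given counts of genes responding in both species, in each species
#' alone, and the total gene universe, computes the expected number of
#' shared responders under independence,
#' `E = (both + a_only)(both + b_only) / total`, the fold excess
#' `both / E`, and the standard Pearson chi-squared statistic (df = 1,
#' no continuity correction) on the implied 2x2 table. Note: the
#' corresponding published chi-squared value is not reproducible from
#' the printed 2x2 counts by the standard formula; this function
#' returns the standard statistic without attempting to guess the
#' original computation.
#'
#' @param both,a_only,b_only,total non-negative counts with
#'   `both + a_only + b_only <= total`, `total > 0`.
#' @return list (expected_both, fold, chi2, df, p); `fold` is `NA`
#'   (flagged) when the expectation is zero.
#' @examples
#' overlap_independence(123, 702, 681, 10443)$expected_both  # 63.5
#' @export
overlap_independence <- function(both, a_only, b_only, total) {
  if (total <= 0) stop("total must be positive")
  if (both + a_only + b_only > total) stop("counts exceed total")
  expected <- (both + a_only) * (both + b_only) / total
  fold <- if (expected > 0) both / expected else NA_real_
  neither <- total - both - a_only - b_only
  O <- matrix(c(both, a_only, b_only, neither), 2, 2)
  rowt <- rowSums(O); colt <- colSums(O)
  E <- outer(rowt, colt) / total
  chi2 <- if (all(E > 0)) sum((O - E)^2 / E) else NA_real_
  p <- if (is.na(chi2)) NA_real_ else pchisq(chi2, df = 1,
                                             lower.tail = FALSE)
  list(expected_both = expected, fold = fold, chi2 = chi2, df = 1L,
       p = p)
}
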