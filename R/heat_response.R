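#' Drop genes with low total read counts
#'
#' Keeps genes whose total count over all samples is strictly greater
#' than `threshold` reads (default 50).
#'
#' @param counts genes x samples count matrix.
#' @param threshold strict lower bound on the per-gene total.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(counts, threshold = 50) {
  counts[rowSums(counts) > threshold, , drop = FALSE]
}

#' TMM per-sample scaling factors
#'
#' Trimmed mean of M-values normalisation (reference sample chosen by
#' upper quartile, 30%/5% two-sided trimming of M and A values,
#' factors scaled to geometric mean 1), delegated to
#' [edgeR::calcNormFactors()].
#'
#' @param counts genes x samples count matrix (no all-zero sample).
#' @return named numeric vector of scaling factors.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(colSums(counts) == 0)) stop("all-zero sample")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' @keywords internal
parse_sample_names <- function(cn) {
  m <- regmatches(cn, regexec("^T([0-9]+)_rep([0-9]+)$", cn))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("sample columns must be named T<k>_rep<r>: ",
                     paste(cn[bad], collapse = ", "))
  data.frame(sample = cn,
             time = paste0("T", vapply(m, `[`, "", 2)),
             rep = vapply(m, `[`, "", 3), stringsAsFactors = FALSE)
}

#' Call heat-responsive genes against the pre-exposure control
#'
#' Computes log2 counts per million (pseudo-count 0.5) on
#' TMM-normalised library sizes, fits a per-gene linear model over the
#' time-point factor and tests each post-control time point against T0
#' with empirical-Bayes moderated t-statistics (gene-wise variances
#' shrunk towards the grand variance prior). Benjamini-Hochberg
#' correction is applied jointly across all gene x time-point tests
#' (per-time-point scope available). A gene is called heat responsive
#' when it has adjusted p < `alpha` and |log2FC| > `lfc` at two or
#' more post-control time points (any sign).
#'
#' @param counts filtered genes x samples count matrix with columns
#'   `T<k>_rep<r>`; T0 is the control.
#' @param factors optional TMM factors (default [tmm_factors()]).
#' @param alpha,lfc,min_timepoints DE criterion parameters.
#' @param adjust_scope `"joint"` (default) or `"per_timepoint"`.
#' @return list with `table` (long data.frame gene, time, logFC, p, q),
#'   `de` (named logical), `logcpm`, and `time_means` (genes x 8 mean
#'   log2cpm per time point).
#' @export
de_call <- function(counts, factors = NULL, alpha = 0.05, lfc = 1,
                    min_timepoints = 2,
                    adjust_scope = c("joint", "per_timepoint")) {
  adjust_scope <- match.arg(adjust_scope)
  info <- parse_sample_names(colnames(counts))
  if (!"T0" %in% info$time) stop("control time point T0 missing")
  reps <- table(info$time)
  if (any(reps < 2)) stop("need >= 2 replicates at every time point")
  if (is.null(factors)) factors <- tmm_factors(counts)
  lib <- colSums(counts) * factors
  logcpm <- edgeR::cpm(counts, lib.size = lib, log = TRUE,
                       prior.count = 0.5)
  tf <- factor(info$time, levels = sort(unique(info$time)))
  design <- stats::model.matrix(~ 0 + tf)
  colnames(design) <- levels(tf)
  fit <- limma::lmFit(logcpm, design)
  post <- setdiff(levels(tf), "T0")
  cm <- vapply(post, function(tp) {
    v <- setNames(numeric(nlevels(tf)), levels(tf))
    v[tp] <- 1; v["T0"] <- -1
    v
  }, numeric(nlevels(tf)))
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  tab <- do.call(rbind, lapply(post, function(tp) {
    data.frame(gene = rownames(counts), time = tp,
               logFC = fit2$coefficients[, tp],
               p = fit2$p.value[, tp], stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab$q <- if (adjust_scope == "joint") p.adjust(tab$p, "BH") else
    stats::ave(tab$p, tab$time, FUN = function(p) p.adjust(p, "BH"))
  hit <- tab$q < alpha & abs(tab$logFC) > lfc
  nhits <- tapply(hit, tab$gene, sum)
  de <- setNames(as.vector(nhits) >= min_timepoints, names(nhits))
  de <- de[rownames(counts)]
  tmeans <- vapply(levels(tf), function(tp) {
    rowMeans(logcpm[, info$time == tp, drop = FALSE])
  }, numeric(nrow(counts)))
  list(table = tab, de = de, logcpm = logcpm, time_means = tmeans)
}

#' Standardise per-gene time-point profiles
#'
#' Z-scores each gene's vector of per-time-point mean log2cpm values
#' (mean 0, sd 1 across the 8 time points). Zero-variance profiles are
#' excluded with a warning.
#'
#' @param time_means genes x time-points matrix.
#' @return standardised matrix (possibly fewer rows).
#' @export
standardize_profiles <- function(time_means) {
  sds <- apply(time_means, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) excluded")
    time_means <- time_means[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (time_means - rowMeans(time_means)) / sds
}

#' Fuzzy c-means clustering of expression trajectories
#'
#' Standard fuzzy c-means with Euclidean distance and fuzzifier `m`:
#' alternate the centroid update (membership^m-weighted means) and the
#' membership update (inverse squared-distance^(1/(m-1)), rows
#' normalised to 1) until the largest centroid shift drops below
#' `tol`. The objective is non-increasing across iterations; the best
#' of `restarts` random initialisations (by final objective) is
#' returned. Deterministic for a fixed seed.
#'
#' @param x profiles matrix (rows = genes).
#' @param c number of clusters (2 <= c < nrow(x)).
#' @param m fuzzifier (> 1), default 2.
#' @param tol convergence tolerance on the centroid shift.
#' @param max_iter iteration cap per restart.
#' @param restarts random restarts.
#' @param seed integer seed.
#' @return list of class `fcm`: `membership` (rows sum to 1),
#'   `centers`, `objective`, `trace` (objective per iteration of the
#'   winning restart), `c`, `m`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, tol = 1e-6, max_iter = 1000,
                         restarts = 5, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c < 2 || c >= n) stop("need 2 <= c < number of profiles")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- x[sample.int(n, c), , drop = FALSE] +
      matrix(rnorm(c * ncol(x), 0, 1e-3), c)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
        2 * x %*% t(centers)
      d2[d2 < 1e-12] <- 1e-12
      u <- d2^(-1 / (m - 1))
      u <- u / rowSums(u)
      um <- u^m
      newc <- t(um) %*% x / colSums(um)
      trace <- c(trace, sum(um * d2))
      shift <- max(abs(newc - centers))
      centers <- newc
      if (shift < tol) break
    }
    obj <- trace[length(trace)]
    if (is.null(best) || obj < best$objective) {
      best <- list(membership = u, centers = centers, objective = obj,
                   trace = trace, c = c, m = m)
    }
  }
  rownames(best$membership) <- rownames(x)
  class(best) <- "fcm"
  best
}

#' Choose the cluster number by the partition coefficient
#'
#' Runs [fuzzy_cmeans()] for each candidate `c` and returns the `c`
#' maximising the fuzzy partition coefficient
#' `PC = mean(rowSums(U^2))` (1 for a crisp partition, `1/c` for a
#' uniform one); ties break to the smaller `c`.
#'
#' @param x profiles matrix.
#' @param c_range candidate cluster numbers, default 4:20.
#' @param ... passed to [fuzzy_cmeans()].
#' @return list with `c` (chosen), `pc` (named vector of partition
#'   coefficients).
#' @export
select_c <- function(x, c_range = 4:20, ...) {
  pc <- vapply(c_range, function(cc) {
    fit <- fuzzy_cmeans(x, cc, ...)
    partition_coefficient(fit$membership)
  }, numeric(1))
  names(pc) <- c_range
  list(c = c_range[which.max(pc)], pc = pc)
}

#' Fuzzy partition coefficient
#' @param membership genes x clusters membership matrix.
#' @return mean squared membership.
#' @export
partition_coefficient <- function(membership) {
  mean(rowSums(membership^2))
}

#' Per-cluster species report: excesses, core and discriminating genes
#'
#' Both species' standardised profiles are assumed to have been pooled
#' before clustering, so all genes share one set of centroids. Core
#' genes have maximum membership > `core_threshold`; genes never
#' exceeding it are reported unclustered. Per cluster the report gives
#' the core-gene counts per species, the excess (count difference and
#' percentage relative to the minority species), and the
#' *discriminating genes*: core genes of the excess species whose 1:1
#' orthologue is not a core gene of the same cluster in the other
#' species (genes without orthologues qualify). The `top_n`
#' highest-membership discriminating genes are listed per cluster
#' (stable tie-break by gene id).
#'
#' @param fcm a [fuzzy_cmeans()] fit on the pooled profiles.
#' @param meta data.frame aligned with the profile rows: columns
#'   `gene_id`, `species` (exactly two species).
#' @param orthologs data.frame (gene_a, gene_b) of 1:1 orthologue
#'   pairs across the two species; clustered genes absent from the map
#'   are treated as having no orthologue (with a warning).
#' @param core_threshold core-membership cut-off, default 0.5.
#' @param top_n number of top discriminating genes per cluster.
#' @return list with `summary` (per-cluster data.frame),
#'   `discriminating` (list: cluster -> gene ids of the excess
#'   species), `top_members` (data.frame cluster, gene_id, species,
#'   membership), `unclustered` (data.frame gene_id, species).
#' @export
cluster_report <- function(fcm, meta, orthologs,
                           core_threshold = 0.5, top_n = 10) {
  u <- fcm$membership
  stopifnot(nrow(u) == nrow(meta))
  sps <- sort(unique(meta$species))
  if (length(sps) != 2) stop("exactly two species expected")
  maxu <- apply(u, 1, max)
  assign <- apply(u, 1, which.max)
  core <- maxu > core_threshold
  unclustered <- meta[!core, c("gene_id", "species")]

  omap <- c(setNames(orthologs$gene_b, orthologs$gene_a),
            setNames(orthologs$gene_a, orthologs$gene_b))
  missing <- setdiff(meta$gene_id, names(omap))
  if (length(missing)) {
    warning(length(missing),
            " clustered gene(s) absent from the orthologue map; ",
            "treated as having no orthologue")
  }

  k <- fcm$c
  summ <- list(); disc <- list(); tops <- list()
  for (cl in seq_len(k)) {
    in_cl <- core & assign == cl
    n_by_sp <- vapply(sps, function(s) sum(in_cl & meta$species == s), 0L)
    excess_sp <- sps[which.max(n_by_sp)]
    other_sp <- setdiff(sps, excess_sp)
    n_exc <- max(n_by_sp); n_oth <- min(n_by_sp)
    pct <- if (n_oth > 0) 100 * (n_exc - n_oth) / n_oth else NA_real_
    ## core genes of the other species in this cluster
    other_core <- meta$gene_id[in_cl & meta$species == other_sp]
    cand <- which(in_cl & meta$species == excess_sp)
    orth <- omap[meta$gene_id[cand]]
    is_disc <- is.na(orth) | !(orth %in% other_core)
    dg <- meta$gene_id[cand][is_disc]
    dm <- u[cand, cl][is_disc]
    ord <- order(-dm, dg)
    disc[[as.character(cl)]] <- dg[ord]
    nt <- min(top_n, length(dg))
    if (nt > 0) {
      tops[[as.character(cl)]] <- data.frame(
        cluster = cl, gene_id = dg[ord][seq_len(nt)],
        species = excess_sp, membership = dm[ord][seq_len(nt)],
        stringsAsFactors = FALSE)
    }
    summ[[cl]] <- data.frame(
      cluster = cl, n_core = sum(in_cl),
      setNames(as.list(n_by_sp), paste0("n_", sps)),
      excess_species = excess_sp, excess = n_exc - n_oth,
      excess_pct = pct, n_discriminating = length(dg),
      stringsAsFactors = FALSE)
  }
  list(summary = do.call(rbind, summ),
       discriminating = disc,
       top_members = if (length(tops)) do.call(rbind, tops) else NULL,
       unclustered = unclustered)
}
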