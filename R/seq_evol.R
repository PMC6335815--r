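#' @keywords internal
seq_to_int <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], .NUC)
  if (anyNA(x)) stop("sequence contains non-ACGT characters")
  x
}

#' @keywords internal
validate_alignment <- function(aln) {
  if (!length(aln)) stop("empty alignment")
  ln <- nchar(aln)
  if (length(unique(ln)) != 1L) stop("unequal sequence lengths")
  if (ln[1] %% 3 != 0) stop("alignment length not divisible by 3")
  aa <- codon_aa_table()
  mats <- lapply(aln, seq_to_int)
  for (nm in names(mats)) {
    v <- mats[[nm]]
    cods <- codon_idx(v[c(TRUE, FALSE, FALSE)], v[c(FALSE, TRUE, FALSE)],
                      v[c(FALSE, FALSE, TRUE)])
    st <- which(aa[cods] == "*")
    if (length(st)) {
      stop(sprintf("internal stop codon in '%s' at codon %d", nm, st[1]))
    }
  }
  mats
}

## prefixes (first two bases) whose codon family is 4-fold degenerate
#' @keywords internal
fourfold_prefixes <- local({
  pf <- NULL
  function() {
    if (is.null(pf)) {
      aa <- codon_aa_table()
      res <- logical(16)
      for (b1 in 1:4) for (b2 in 1:4) {
        aas <- aa[codon_idx(b1, b2, 1:4)]
        res[4 * (b1 - 1) + b2] <- length(unique(aas)) == 1L &&
          !any(aas == "*")
      }
      pf <<- res
    }
    pf
  }
})

#' Third-position columns of 4-fold degenerate codons
#'
#' Returns the (1-based, nucleotide) indices of third codon positions
#' at which, in *every* sequence of the alignment, the first two bases
#' of the codon place it in a 4-fold degenerate codon family of the
#' standard genetic code (so the third base is silent whatever it is).
#' The strict intersection across sequences avoids counting sites whose
#' degeneracy class differs between species.
#'
#' @param aln named character vector of equal-length, gap-free coding
#'   sequences (A/C/G/T, length divisible by 3, no internal stops).
#' @return integer vector of third-position column indices.
#' @export
fourfold_degenerate_columns <- function(aln) {
  mats <- validate_alignment(aln)
  ncod <- nchar(aln[[1]]) %/% 3
  pf <- fourfold_prefixes()
  ok <- rep(TRUE, ncod)
  for (v in mats) {
    b1 <- v[c(TRUE, FALSE, FALSE)]
    b2 <- v[c(FALSE, TRUE, FALSE)]
    ok <- ok & pf[4 * (b1 - 1) + b2]
  }
  which(ok) * 3L
}

#' Jukes-Cantor silent distances over 4-fold degenerate columns
#'
#' For each sequence pair, `p` is the mismatch fraction over the given
#' 4-fold columns and the distance is the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)`. Pairs at or beyond the correction's
#' domain boundary (`p >= 3/4`) are flagged saturated and returned as
#' `NA` (excluded from downstream fitting).
#'
#' @param aln named character vector of aligned coding sequences.
#' @param columns third-position column indices, e.g. from
#'   [fourfold_degenerate_columns()].
#' @return symmetric distance matrix with a logical `"saturated"`
#'   attribute of the same shape.
#' @export
jc_silent_distance <- function(aln, columns) {
  if (!length(columns)) stop("no usable 4-fold degenerate columns")
  mats <- lapply(aln, seq_to_int)
  third <- vapply(mats, function(v) v[columns], integer(length(columns)))
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(third[, i] != third[, j])
    if (p >= 0.75) {
      d[i, j] <- d[j, i] <- NA_real_
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Least-squares branch lengths on a fixed topology
#'
#' Fits non-negative branch lengths to a matrix of pairwise distances
#' by least squares on the fixed species topology (each pairwise
#' distance is the sum of the branch lengths on the path between the
#' two tips). Saturated (`NA`) pairs are dropped from the fit.
#'
#' Pairwise distances cannot place the root: the two root-adjacent
#' branches appear in every path together, so only their sum is
#' estimable. The fit therefore merges them into one parameter and
#' splits the fitted sum equally between the two; their ids are
#' reported in the `"root_spanning"` attribute and should be excluded
#' from per-branch comparisons.
#'
#' @param tree rooted topology ([ape::phylo], node-labelled) covering
#'   all taxa of `dmat`.
#' @param dmat symmetric pairwise distance matrix (row/col names are
#'   tip labels).
#' @return named numeric vector of branch lengths (names are branch
#'   ids as in [branch_table()]), with attributes `"residual"` (the
#'   residual norm of the fit) and `"root_spanning"`.
#' @export
ls_branch_lengths <- function(tree, dmat) {
  tree <- ensure_node_labels(tree)
  taxa <- rownames(dmat)
  if (length(taxa) < 3) stop("need >= 3 taxa to fit branch lengths")
  if (!all(taxa %in% tree$tip.label)) stop("topology does not cover all taxa")
  if (!all(tree$tip.label %in% taxa)) {
    tree <- ape::keep.tip(tree, taxa)
    tree <- ensure_node_labels(tree)
  }
  bt <- branch_table(tree)
  pairs <- t(utils::combn(length(taxa), 2))
  tipno <- match(taxa, tree$tip.label)
  nb <- nrow(bt)
  A <- matrix(0, nrow(pairs), nb)
  y <- numeric(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    y[r] <- dmat[taxa[i], taxa[j]]
    keep[r] <- is.finite(y[r])
    np <- ape::nodepath(tree, tipno[i], tipno[j])
    for (s in seq_len(length(np) - 1)) {
      e <- which((tree$edge[, 1] == np[s] & tree$edge[, 2] == np[s + 1]) |
                 (tree$edge[, 1] == np[s + 1] & tree$edge[, 2] == np[s]))
      A[r, e] <- 1
    }
  }
  ## merge the two root-adjacent branches (identical design columns)
  root_edges <- which(tree$edge[, 1] == length(tree$tip.label) + 1L)
  root_branches <- bt$branch[match(root_edges, bt$edge_row)]
  merged <- seq_len(nb)
  if (length(root_edges) == 2) {
    A[, root_edges[1]] <- A[, root_edges[1]] + 0 * A[, root_edges[2]]
    Am <- A[, -root_edges[2], drop = FALSE]
    keep_cols <- setdiff(seq_len(nb), root_edges[2])
  } else {
    Am <- A
    keep_cols <- seq_len(nb)
  }
  if (sum(keep) < ncol(Am)) {
    stop("underdetermined system after dropping saturated pairs")
  }
  fit <- pracma::lsqnonneg(Am[keep, , drop = FALSE], y[keep])
  bl <- setNames(rep(NA_real_, nb), bt$branch)
  bl[keep_cols] <- fit$x
  if (length(root_edges) == 2) {
    bl[root_edges] <- bl[root_edges[1]] / 2
  }
  attr(bl, "residual") <- sqrt(fit$resid.norm)
  attr(bl, "root_spanning") <- root_branches
  bl
}

## --- NG86 Ka/Ks ------------------------------------------------------------

#' @keywords internal
ng86_site_counts <- function(cod, aa) {
  ## synonymous site count of one codon: per position, fraction of the
  ## three possible changes that are synonymous (stop-producing changes
  ## count as nonsynonymous)
  s <- 0
  for (pos in 1:3) {
    b <- cod
    for (alt in setdiff(1:4, cod[pos])) {
      b[pos] <- alt
      if (aa[codon_idx(b[1], b[2], b[3])] ==
          aa[codon_idx(cod[1], cod[2], cod[3])]) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

#' @keywords internal
ng86_pathways <- function(c1, c2, aa) {
  ## average synonymous / nonsynonymous difference counts over all
  ## minimal substitution pathways between two codons; pathways passing
  ## through a stop codon are excluded (if all are blocked, fall back
  ## to all pathways, counting stop steps as nonsynonymous)
  diffpos <- which(c1 != c2)
  nd <- length(diffpos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(diffpos) else {
    pm <- permutations_of(diffpos)
    pm
  }
  tally <- function(skip_stops) {
    tot_s <- 0; tot_n <- 0; used <- 0
    for (ord in perms) {
      cur <- c1
      s <- 0; n <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- c2[pos]
        a1 <- aa[codon_idx(cur[1], cur[2], cur[3])]
        a2 <- aa[codon_idx(nxt[1], nxt[2], nxt[3])]
        if (a2 == "*" && skip_stops) { ok <- FALSE; break }
        if (a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; used <- used + 1 }
    }
    if (used == 0) return(NULL)
    c(sd = tot_s / used, nd = tot_n / used)
  }
  res <- tally(TRUE)
  if (is.null(res)) res <- tally(FALSE)
  res
}

#' @keywords internal
permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Nei-Gojobori (1986) Ka/Ks for a codon sequence pair
#'
#' Classical NG86: synonymous and nonsynonymous site counts per codon
#' (fraction of the three possible changes at each position that are
#' synonymous), averaged over the two sequences; observed differences
#' averaged over all minimal substitution pathways between differing
#' codons, excluding pathways through stop codons; Jukes-Cantor
#' correction of the proportions. The ratio is undefined (`NA`) when
#' `Ks = 0`.
#'
#' @param seq1,seq2 equal-length gap-free coding sequences (characters,
#'   A/C/G/T, no internal stops).
#' @return list with `Ka`, `Ks`, `ratio`, and the underlying site and
#'   difference counts `N`, `S`, `Nd`, `Sd`.
#' @export
ng86_kaks <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) stop("sequence length mismatch")
  mats <- validate_alignment(c(a = seq1, b = seq2))
  v1 <- mats[[1]]; v2 <- mats[[2]]
  aa <- codon_aa_table()
  ncod <- length(v1) %/% 3L
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(ncod)) {
    o <- 3L * (k - 1L)
    c1 <- v1[(o + 1L):(o + 3L)]
    c2 <- v2[(o + 1L):(o + 3L)]
    S <- S + (ng86_site_counts(c1, aa) + ng86_site_counts(c2, aa)) / 2
    if (any(c1 != c2)) {
      pw <- ng86_pathways(c1, c2, aa)
      Sd <- Sd + pw[["sd"]]
      Nd <- Nd + pw[["nd"]]
    }
  }
  N <- 3 * ncod - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  list(Ka = Ka, Ks = Ks, ratio = ratio, N = N, S = S, Nd = Nd, Sd = Sd)
}

#' Four-criterion orthogroup filter for phylogenomics
#'
#' Applies, in order, the orthogroup retention criteria used to select
#' loci for species-tree estimation: (1) no traceable duplications
#' (orthogroups that generated inparalogues are rejected); (2) slow
#' evolution, no member-vs-reference pair with Ka/Ks > 1; (3) proteins
#' longer than 200 aa, unless all members are within five residues of
#' each other; (4) every member length within 1.5 median absolute
#' deviations of the median length (raw MAD, floored at one residue so
#' near-identical length sets are not rejected by a degenerate MAD of
#' zero).
#'
#' @param alignments named list: orthogroup id -> named character
#'   vector (species -> codon sequence).
#' @param has_inparalogue named logical: orthogroup id -> whether any
#'   member generated inparalogues.
#' @param lengths_aa optional named list of per-member protein lengths
#'   (aa); defaults to alignment length / 3.
#' @param reference species name of the designated reference member for
#'   the Ka/Ks criterion (first member if absent).
#' @param kaks_max,min_aa,len_window,mad_mult criterion thresholds.
#' @return data.frame (orthogroup_id, retained, rejected_by) where
#'   `rejected_by` is `NA` or one of `"duplications"`, `"kaks"`,
#'   `"length"`, `"mad"`.
#' @export
filter_orthogroups_for_phylogeny <- function(alignments, has_inparalogue,
                                             lengths_aa = NULL,
                                             reference = "Dmel",
                                             kaks_max = 1, min_aa = 200,
                                             len_window = 5,
                                             mad_mult = 1.5) {
  ids <- names(alignments)
  res <- data.frame(orthogroup_id = ids, retained = FALSE,
                    rejected_by = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(ids)) {
    id <- ids[r]
    aln <- alignments[[id]]
    ## (1) duplications
    if (isTRUE(has_inparalogue[[id]])) {
      res$rejected_by[r] <- "duplications"; next
    }
    ## (2) Ka/Ks against the reference member
    ref <- if (reference %in% names(aln)) reference else names(aln)[1]
    bad <- FALSE
    for (sp in setdiff(names(aln), ref)) {
      kk <- ng86_kaks(aln[[ref]], aln[[sp]])
      ## Ka > 0 with Ks = 0 is an unbounded ratio and fails the bound
      high <- (!is.na(kk$ratio) && kk$ratio > kaks_max) ||
        (is.na(kk$ratio) && !is.na(kk$Ka) && kk$Ka > 0 &&
           !is.na(kk$Ks) && kk$Ks == 0)
      if (high) { bad <- TRUE; break }
    }
    if (bad) { res$rejected_by[r] <- "kaks"; next }
    ## (3) length, with the within-five-residues exception
    len <- if (!is.null(lengths_aa)) lengths_aa[[id]] else
      rep(nchar(aln[[1]]) / 3, length(aln))
    if (!(min(len) > min_aa) && (max(len) - min(len) > len_window)) {
      res$rejected_by[r] <- "length"; next
    }
    ## (4) MAD criterion
    md <- median(len)
    bound <- max(mad_mult * mad(len, constant = 1), 1)
    if (any(abs(len - md) > bound)) { res$rejected_by[r] <- "mad"; next }
    res$retained[r] <- TRUE
  }
  res
}

#' Concatenate retained alignments into a supermatrix
#'
#' Concatenates alignments in deterministic (sorted orthogroup id)
#' order and reports 1-based inclusive per-gene coordinate ranges in
#' the standard partition-file convention.
#'
#' @param alignments named list of alignments; every alignment must
#'   contain the full common taxon set.
#' @return list with `matrix` (named character vector: taxon ->
#'   concatenated sequence), `partitions` (data.frame orthogroup_id,
#'   start, end) and `partition_text` (RAxML-style lines).
#' @export
export_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("no retained alignments to concatenate")
  ids <- sort(names(alignments))
  taxa <- sort(names(alignments[[ids[1]]]))
  for (id in ids) {
    miss <- setdiff(taxa, names(alignments[[id]]))
    extra <- setdiff(names(alignments[[id]]), taxa)
    if (length(miss) || length(extra)) {
      stop(sprintf("orthogroup '%s' taxon set mismatch (missing: %s)",
                   id, paste(c(miss, extra), collapse = ", ")))
    }
  }
  pieces <- lapply(taxa, function(tx) {
    paste(vapply(ids, function(id) alignments[[id]][[tx]], ""),
          collapse = "")
  })
  supermat <- setNames(unlist(pieces), taxa)
  lens <- vapply(ids, function(id) nchar(alignments[[id]][[1]]), 0)
  end <- cumsum(lens)
  start <- end - lens + 1
  parts <- data.frame(orthogroup_id = ids, start = start, end = end,
                      stringsAsFactors = FALSE)
  rownames(parts) <- NULL
  txt <- sprintf("DNA, %s = %d-%d", ids, start, end)
  list(matrix = supermat, partitions = parts, partition_text = txt)
}
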