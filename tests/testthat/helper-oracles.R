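## Independent oracles used by the tests. These deliberately do not
## share code with the package implementations they check.

NUCS <- c("A", "C", "G", "T")

## translate a codon string via seqinr (independent genetic-code
## source); memoised over the 64 codons for speed
.oracle_code <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      cods <- apply(expand.grid(NUCS, NUCS, NUCS), 1, paste0,
                    collapse = "")
      tab <<- setNames(vapply(cods, function(cd) {
        seqinr::translate(seqinr::s2c(tolower(cd)))
      }, ""), cods)
    }
    tab
  }
})

oracle_translate <- function(codon) .oracle_code()[[codon]]

## is a codon 4-fold degenerate? brute force over third bases
oracle_is_fourfold <- function(codon) {
  aas <- vapply(NUCS, function(b) {
    oracle_translate(paste0(substr(codon, 1, 2), b))
  }, "")
  length(unique(aas)) == 1 && !any(aas == "*")
}

## NG86 synonymous site count of one codon, brute force
oracle_syn_sites <- function(codon) {
  aa0 <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) == aa0) s <- s + 1 / 3
    }
  }
  s
}

## NG86 pathway-averaged difference counts, explicit enumeration
oracle_pathways <- function(c1, c2) {
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  perms <- perms_list(diffpos)
  paths <- lapply(perms, function(ord) {
    cur <- c1
    steps <- list()
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      steps[[length(steps) + 1]] <- c(cur, nxt)
      cur <- nxt
    }
    steps
  })
  score <- function(steps, allow_stop) {
    s <- 0; n <- 0
    for (st in steps) {
      a1 <- oracle_translate(st[1]); a2 <- oracle_translate(st[2])
      if (a2 == "*" && !allow_stop) return(NULL)
      if (a1 == a2) s <- s + 1 else n <- n + 1
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(paths, score, allow_stop = FALSE))
  if (!length(res)) res <- lapply(paths, score, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

perms_list <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (r in perms_list(x[-i])) out[[length(out) + 1]] <- c(x[i], r)
  }
  out
}

## full NG86 oracle for a pair of codon sequences
oracle_ng86 <- function(s1, s2) {
  cod1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cod2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  S <- sum(vapply(seq_along(cod1), function(i) {
    (oracle_syn_sites(cod1[i]) + oracle_syn_sites(cod2[i])) / 2
  }, 0))
  N <- 3 * length(cod1) - S
  dif <- vapply(seq_along(cod1), function(i) {
    oracle_pathways(cod1[i], cod2[i])
  }, c(sd = 0, nd = 0))
  Sd <- sum(dif["sd", ]); Nd <- sum(dif["nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(if (N > 0) Nd / N else 0),
       Ks = jc(if (S > 0) Sd / S else 0), S = S, N = N, Sd = Sd, Nd = Nd)
}

## Clopper-Pearson by bisection on the exact binomial tails
oracle_cp <- function(x, n, conf = 0.95, tol = 1e-12) {
  a <- (1 - conf) / 2
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a, 0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) a - pbinom(x, n, p), 0, 1)
  c(lower = lower, upper = upper)
}

## hypergeometric upper tail by direct summation
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

## all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) { out[[length(out) + 1]] <<- rgs; return() }
    for (v in 1:(mx + 1)) rec(c(rgs, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

## small fixed species-tree fixtures
two_species_tree <- function() {
  aridEvol:::ensure_node_labels(ape::read.tree(text = "(A:1,B:1)root;"))
}
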