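# Independent oracles: deliberately naive re-derivations of every operation
# under test, written with plain loops against the definitions, so they share
# no code path with the package implementation.

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# quadratic affine-gap local alignment, score only (Gotoh, matrices in R)
oracle_sw_score <- function(a, b, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      M[i, j] <- max(0, M[i - 1, j - 1] + b62[av[i - 1], bv[j - 1]],
                     X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# best hits per query by scanning rows, bitscores rounded to 1 decimal
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    d <- hits[hits$query_id == q, , drop = FALSE]
    r <- round(d$bitscore, 1)
    out[[q]] <- sort(unique(d$subject_id[r == max(r)]))
  }
  out
}

# full naive orthology resolution: unique BRH seed, then fixpoint passes in
# ascending rank of the genome-A gene; anchors are the pairs accepted before
# the pass began; a candidate fires when it is the only anchored option for
# its gene and both genes are still free.
oracle_orthology <- function(hits_ab, hits_ba, rank_a, rank_b, max_gap = 2) {
  BA <- oracle_best_hits(hits_ab)
  BB <- oracle_best_hits(hits_ba)
  seed <- list()
  for (a in names(BA)) {
    if (length(BA[[a]]) == 1) {
      b <- BA[[a]]
      if (!is.null(BB[[b]]) && length(BB[[b]]) == 1 && BB[[b]] == a) {
        seed[[length(seed) + 1]] <- c(a, b)
      }
    }
  }
  seed_keys <- vapply(seed, paste, character(1), collapse = " ")
  cands <- list()
  for (a in names(BA)) {
    for (b in BA[[a]]) {
      if (!is.null(BB[[b]]) && a %in% BB[[b]] &&
          !(paste(a, b) %in% seed_keys)) {
        cands[[length(cands) + 1]] <- c(a, b)
      }
    }
  }
  accepted <- seed
  used_a <- vapply(seed, `[`, character(1), 1)
  used_b <- vapply(seed, `[`, character(1), 2)
  cands <- Filter(function(p) !(p[1] %in% used_a) && !(p[2] %in% used_b),
                  cands)
  resolved <- list()
  g1 <- max_gap + 1
  repeat {
    anchors <- accepted
    changed <- FALSE
    as_left <- unique(vapply(cands, `[`, character(1), 1))
    for (a in as_left[order(rank_a[as_left])]) {
      mine <- Filter(function(p) p[1] == a, cands)
      if (!length(mine)) next
      dist <- vapply(mine, function(p) {
        best <- Inf
        for (q in anchors) {
          da <- abs(rank_a[[p[1]]] - rank_a[[q[1]]])
          db <- abs(rank_b[[p[2]]] - rank_b[[q[2]]])
          if (da > 0 && da <= g1 && db > 0 && db <= g1) {
            best <- min(best, max(da, db))
          }
        }
        best
      }, numeric(1))
      winner <- which(is.finite(dist) & dist == min(dist))
      if (length(winner) == 1) {
        p <- mine[[winner]]
        accepted <- c(accepted, list(p))
        resolved <- c(resolved, list(p))
        cands <- Filter(function(q) q[1] != p[1] && q[2] != p[2], cands)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  df <- data.frame(
    feature_a = vapply(accepted, `[`, character(1), 1),
    feature_b = vapply(accepted, `[`, character(1), 2),
    stage = c(rep("brh_unique", length(seed)),
              rep("synteny_resolved", length(resolved))),
    stringsAsFactors = FALSE)
  df[order(df$feature_a), , drop = FALSE]
}

# exhaustive maximal gap-bounded colinear chaining: enumerate every valid
# chain by recursion from every start pair, keep the maximal ones
oracle_chains <- function(pairs, max_gap = 2) {
  # pairs: data.frame feature_a, feature_b, rank_a, rank_b (single replicon)
  p <- pairs[order(pairs$rank_a), , drop = FALSE]
  n <- nrow(p)
  if (n < 2) return(list())
  mapped_b <- sort(p$rank_b)
  linkable <- function(i, j, sgn) {
    # j must be the next mapped gene after i in A
    if (j != i + 1) return(FALSE)
    if (p$rank_a[j] - p$rank_a[i] - 1 > max_gap) return(FALSE)
    lo <- min(p$rank_b[i], p$rank_b[j]); hi <- max(p$rank_b[i], p$rank_b[j])
    if (any(mapped_b > lo & mapped_b < hi)) return(FALSE)
    if (hi - lo - 1 > max_gap) return(FALSE)
    sign(p$rank_b[j] - p$rank_b[i]) == sgn
  }
  chains <- list()
  extend <- function(chain, sgn) {
    i <- chain[length(chain)]
    grew <- FALSE
    for (j in seq_len(n)) {
      if (linkable(i, j, sgn)) {
        extend(c(chain, j), sgn)
        grew <- TRUE
      }
    }
    if (!grew && length(chain) >= 2) {
      chains[[length(chains) + 1]] <<- list(rows = chain, sgn = sgn)
    }
  }
  for (s in seq_len(n)) {
    for (sgn in c(1, -1)) {
      # only start chains that cannot be extended to the left
      left_ext <- any(vapply(seq_len(n), function(i) linkable(i, s, sgn),
                             logical(1)))
      if (!left_ext) extend(s, sgn)
    }
  }
  lapply(chains, function(ch) {
    list(feature_a = p$feature_a[ch$rows], feature_b = p$feature_b[ch$rows],
         orientation = ch$sgn)
  })
}

# direct GOC recount for one genome of a pair; `pairs` must be oriented so
# feature_a belongs to `genome` (swap columns for the B side)
oracle_goc <- function(genome, partner, pairs, window_frac = 0.03) {
  part <- setNames(pairs$feature_b, pairs$feature_a)
  prank <- setNames(partner$features$rank, partner$features$feature_id)
  res <- NULL
  repl <- genome$replicons$replicon_id[1]
  len <- genome$replicons$length_bp[1]
  f <- genome$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$rank), , drop = FALSE]
  w <- max(1, round(window_frac * len))
  step <- max(1, round(w / 4))
  mid <- (cds$start + cds$end) / 2
  n <- nrow(cds)
  adj <- rep(FALSE, n)
  for (k in seq_len(n - 1)) {
    pk <- unname(part[cds$feature_id[k]])
    pn <- unname(part[cds$feature_id[k + 1]])
    if (!is.na(pk) && !is.na(pn) &&
        abs(prank[[pn]] - prank[[pk]]) == 1) adj[k] <- TRUE
  }
  for (s in seq(1, max(1, len - w + 1), by = step)) {
    inw <- which(mid >= s & mid <= s + w - 1 & seq_len(n) < n)
    if (!length(inw)) next
    res <- rbind(res, data.frame(window_start_bp = s,
                                 goc = sum(adj[inw]) / length(inw)))
  }
  res
}
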