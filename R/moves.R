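## Topology proposals for the Metropolis-Hastings sampler. Each returns
## NULL (an immediate reject / no-op) or a list with the proposed tree,
## the log Hastings ratio log q(x|x') - log q(x'|x), and for the
## sampled-ancestor toggle the remapped clock state.

## ordered (p, c) pairs eligible for a narrow exchange: p a bifurcation
## whose parent g is also a bifurcation, with sibling s younger than p
narrow_pairs <- function(tr) {
  out <- matrix(0L, 0L, 2L)
  for (p in bifurcation_nodes(tr)) {
    g <- tr$parent[p]
    if (is.na(g) || tr$is_sample[g]) next
    s <- setdiff(children_of(tr, g), p)
    if (length(s) != 1L) next
    if (tr$age[p] <= tr$age[s]) next
    for (c in children_of(tr, p)) out <- rbind(out, c(p, c))
  }
  out
}

## swap the sibling of p with one of p's children; ages unchanged
propose_narrow_exchange <- function(tr) {
  E <- narrow_pairs(tr)
  if (!nrow(E)) return(NULL)
  pick <- E[sample.int(nrow(E), 1L), ]
  p <- pick[1L]; c <- pick[2L]
  g <- tr$parent[p]
  s <- setdiff(children_of(tr, g), p)
  tr$parent[s] <- p
  tr$parent[c] <- g
  E2 <- narrow_pairs(tr)
  if (!nrow(E2)) return(NULL)
  list(tree = sa_tree(tr$parent, tr$age, tr$is_sample, tr$label, tr$origin_age),
       log_hastings = log(nrow(E)) - log(nrow(E2)))
}

## nodes in the subtree rooted at nd (inclusive)
subtree_nodes <- function(tr, nd) {
  out <- nd
  frontier <- nd
  while (length(frontier)) {
    kids <- which(!is.na(tr$parent) & tr$parent %in% frontier)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

## count of prunable nodes: non-root nodes whose parent is a bifurcation
n_prunable <- function(tr) {
  nr <- which(!is.na(tr$parent))
  sum(!tr$is_sample[tr$parent[nr]])
}

## Wilson-Balding-style subtree regraft: lift the parent bifurcation of
## a random node and re-insert it on a random eligible branch at a
## uniform age. The lifted node keeps its identity (and branch rate).
propose_spr <- function(tr) {
  nr <- which(!is.na(tr$parent))
  prunable <- nr[!tr$is_sample[tr$parent[nr]]]
  if (!length(prunable)) return(NULL)
  nP <- length(prunable)
  i <- prunable[sample.int(nP, 1L)]
  p <- tr$parent[i]
  j0 <- setdiff(children_of(tr, p), i)
  if (length(j0) != 1L) return(NULL)
  g <- tr$parent[p]
  ## detach: j0 takes p's place
  det <- tr
  det$parent[j0] <- g
  det$parent[p] <- NA_integer_         # dangling, ignored below
  excluded <- c(subtree_nodes(det, i), p)
  cand <- setdiff(seq_along(det$parent), excluded)
  topage <- vapply(cand, function(j) {
    pj <- det$parent[j]
    if (is.na(pj) || pj == p) det$origin_age else det$age[pj]
  }, 0)
  lo <- pmax(tr$age[i], det$age[cand])
  ok <- topage > lo
  cand <- cand[ok]; topage <- topage[ok]; lo <- lo[ok]
  if (!length(cand)) return(NULL)
  pick <- sample.int(length(cand), 1L)
  j <- cand[pick]
  len_fwd <- topage[pick] - lo[pick]
  u <- stats::runif(1L, lo[pick], topage[pick])
  ## reverse window: re-insertion above j0
  pj0 <- det$parent[j0]
  top0 <- if (is.na(pj0) || pj0 == p) det$origin_age else det$age[pj0]
  len_rev <- top0 - max(tr$age[i], det$age[j0])
  if (len_rev <= 0) return(NULL)
  ## attach p above j at age u
  new <- det
  new$parent[p] <- new$parent[j]
  new$parent[j] <- p
  new$age[p] <- u
  out <- sa_tree(new$parent, new$age, new$is_sample, new$label, new$origin_age)
  list(tree = out,
       log_hastings = log(len_fwd) - log(len_rev) +
         log(nP) - log(n_prunable(out)))
}

## log proposal density of a new branch rate / category under the
## current clock hyperparameters (the same form the prior uses, so the
## dimension-changing factors cancel correctly in the toggle move)
clock_rate_proposal <- function(clock, value = NULL) {
  if (clock$model == "ulnc") {
    ml <- log(clock$M) - clock$S^2 / 2
    if (is.null(value)) {
      v <- stats::rlnorm(1L, ml, clock$S)
      list(value = v, logd = stats::dlnorm(v, ml, clock$S, log = TRUE))
    } else {
      list(value = value, logd = stats::dlnorm(value, ml, clock$S, log = TRUE))
    }
  } else if (clock$model == "ncat2") {
    if (is.null(value)) list(value = sample(1:2, 1L), logd = log(0.5))
    else list(value = value, logd = log(0.5))
  } else {
    list(value = NA_real_, logd = 0)
  }
}

## reversible-jump toggle between a terminal sample and a sampled
## ancestor; handles the per-branch clock parameter born/killed with
## the lifted bifurcation
propose_sa_toggle <- function(tr, clock) {
  to_sa <- stats::runif(1L) < 0.5
  if (to_sa) {
    conv <- convertible_tips(tr)
    if (!length(conv)) return(NULL)
    i <- conv[sample.int(length(conv), 1L)]
    p <- tr$parent[i]
    g <- tr$parent[p]
    top <- if (is.na(g)) tr$origin_age else tr$age[g]
    len <- top - tr$age[i]
    old_par <- clock_branch_value(clock, p)
    res <- toggle_tip_to_sa(tr, i)
    if (is.null(res)) return(NULL)
    newclock <- clock_subset(clock, res$kept)
    prop_old <- clock_rate_proposal(clock, old_par)
    n_sa_new <- length(sa_nodes(res$tree))
    lh <- (-log(n_sa_new) - log(len) + prop_old$logd) - (-log(length(conv)))
    list(tree = res$tree, clock = newclock, log_hastings = lh)
  } else {
    sas <- sa_nodes(tr)
    if (!length(sas)) return(NULL)
    z <- sas[sample.int(length(sas), 1L)]
    g <- tr$parent[z]
    top <- if (is.na(g)) tr$origin_age else tr$age[g]
    len <- top - tr$age[z]
    if (len <= 0) return(NULL)
    u <- stats::runif(1L, tr$age[z], top)
    res <- toggle_sa_to_tip(tr, z, u)
    if (is.null(res)) return(NULL)
    draw <- clock_rate_proposal(clock)
    newclock <- clock_append(clock, draw$value)
    conv_new <- length(convertible_tips(res$tree))
    if (!conv_new) return(NULL)
    lh <- (-log(conv_new)) - (-log(length(sas)) - log(len) + draw$logd)
    list(tree = res$tree, clock = newclock, log_hastings = lh)
  }
}

clock_branch_value <- function(clock, node) {
  switch(clock$model,
         ulnc = clock$rates[node],
         ncat2 = clock$categories[node],
         strict = NA_real_)
}

clock_subset <- function(clock, kept) {
  if (clock$model == "ulnc") clock$rates <- clock$rates[kept]
  else if (clock$model == "ncat2") clock$categories <- clock$categories[kept]
  clock
}

clock_append <- function(clock, value) {
  if (clock$model == "ulnc") clock$rates <- c(clock$rates, value)
  else if (clock$model == "ncat2")
    clock$categories <- c(clock$categories, as.integer(value))
  clock
}
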