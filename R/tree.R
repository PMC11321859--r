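#' Time-calibrated trees with sampled ancestors
#'
#' An `sa_tree` stores a sampled tree from a birth-death-sampling
#' process: nodes carry an age (ka before the sampling present, larger =
#' older), a parent pointer, a sample flag and a label. Sampled
#' ancestors — samples that lie on an internal lineage rather than at a
#' terminus — are represented as degree-2 nodes carrying a sample label;
#' the conventional zero-length side branch is only used when writing
#' Newick. The origin of the process is stored separately as
#' `origin_age` (>= root age).
#'
#' Node types by degree: terminal sample (0 children, sample flag),
#' sampled ancestor (1 child, sample flag), bifurcation (2 children, not
#' a sample).
#'
#' @param parent integer vector; `parent[i]` is the parent node of node
#'   i, `NA` for the root.
#' @param age numeric node ages (ka, present = 0).
#' @param is_sample logical sample flags.
#' @param label node labels (sample ids); `NA` allowed for unsampled
#'   internal nodes.
#' @param origin_age age at which the process originated.
#' @return Object of class `sa_tree`.
#' @export
sa_tree <- function(parent, age, is_sample, label = NULL, origin_age) {
  n <- length(parent)
  stopifnot(length(age) == n, length(is_sample) == n)
  if (is.null(label)) label <- rep(NA_character_, n)
  tr <- structure(list(parent = as.integer(parent), age = as.numeric(age),
                       is_sample = as.logical(is_sample),
                       label = as.character(label),
                       origin_age = as.numeric(origin_age)),
                  class = "sa_tree")
  validate_sa_tree(tr)
  tr
}

#' @export
print.sa_tree <- function(x, ...) {
  cat(sprintf("<sa_tree> %d samples (%d tips, %d sampled ancestors), root %.3f, origin %.3f\n",
              sum(x$is_sample), length(tip_nodes(x)), length(sa_nodes(x)),
              x$age[root_node(x)], x$origin_age))
  invisible(x)
}

n_children <- function(tr) tabulate(tr$parent[!is.na(tr$parent)], nbins = length(tr$parent))

root_node <- function(tr) which(is.na(tr$parent))

## terminal samples
tip_nodes <- function(tr) which(tr$is_sample & n_children(tr) == 0L)

## degree-2 samples along lineages
sa_nodes <- function(tr) which(tr$is_sample & n_children(tr) == 1L)

## unsampled bifurcations
bifurcation_nodes <- function(tr) which(!tr$is_sample & n_children(tr) == 2L)

children_of <- function(tr, node) which(!is.na(tr$parent) & tr$parent == node)

validate_sa_tree <- function(tr) {
  n <- length(tr$parent)
  if (n < 1L) stop("empty tree")
  r <- root_node(tr)
  if (length(r) != 1L) stop("tree must have exactly one root")
  nc <- n_children(tr)
  if (any(nc > 2L)) stop("nodes may have at most two children")
  bad <- which(!tr$is_sample & nc != 2L)
  if (length(bad)) stop("unsampled nodes must be bifurcations (2 children)")
  if (any(tr$is_sample & nc == 2L)) stop("a sample cannot be a bifurcation node")
  notroot <- which(!is.na(tr$parent))
  if (any(tr$age[tr$parent[notroot]] <= tr$age[notroot]))
    stop("parent ages must strictly exceed child ages")
  if (tr$origin_age < tr$age[r]) stop("origin_age must be >= root age")
  if (any(tr$age < 0)) stop("node ages must be >= 0")
  ## reachability (no cycles)
  depth <- rep(NA_integer_, n); depth[r] <- 0L
  frontier <- r
  while (length(frontier)) {
    kids <- which(!is.na(tr$parent) & tr$parent %in% frontier)
    kids <- kids[is.na(depth[kids])]
    depth[kids] <- 1L
    frontier <- kids
  }
  if (anyNA(depth)) stop("tree has unreachable nodes")
  invisible(tr)
}

## branch duration above each node (NA for root); the stem above the
## root (origin to root) is not part of the branch set.
branch_durations <- function(tr) {
  d <- rep(NA_real_, length(tr$parent))
  nr <- which(!is.na(tr$parent))
  d[nr] <- tr$age[tr$parent[nr]] - tr$age[nr]
  d
}

## nodes in post-order (children before parents): parent ages strictly
## exceed child ages, so ascending age order is a valid post-order
postorder <- function(tr) order(tr$age)

## children indexed by node, as a list (NULL when childless)
children_list <- function(tr) {
  nr <- which(!is.na(tr$parent))
  ch <- vector("list", length(tr$parent))
  sp <- split(nr, tr$parent[nr])
  ch[as.integer(names(sp))] <- sp
  ch
}

## sample labels in a fixed order (tips and sampled ancestors)
sample_labels <- function(tr) tr$label[which(tr$is_sample)]

#' Write an `sa_tree` as a Newick string
#'
#' Sampled ancestors are rendered as zero-length side branches: a
#' degree-2 sample at age z becomes a bifurcation at z with the sample
#' attached by a zero-length branch — the conventional file
#' representation for sampled-ancestor trees.
#'
#' @param tr an [sa_tree].
#' @param digits branch-length digits.
#' @return Newick string (with trailing semicolon).
#' @export
write_sa_newick <- function(tr, digits = 10L) {
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    kids <- children_of(tr, node)
    if (!length(kids)) return(tr$label[node])
    if (tr$is_sample[node]) {
      ## sampled ancestor: render as (child, self:0)
      sub <- sprintf("%s:%s", rec(kids), fmt(tr$age[node] - tr$age[kids]))
      sprintf("(%s,%s:0)", sub, tr$label[node])
    } else {
      parts <- vapply(kids, function(k)
        sprintf("%s:%s", rec(k), fmt(tr$age[node] - tr$age[k])), "")
      sprintf("(%s)", paste(parts, collapse = ","))
    }
  }
  r <- root_node(tr)
  paste0(rec(r), ":", fmt(tr$origin_age - tr$age[r]), ";")
}

#' Read a Newick string into an `sa_tree`
#'
#' The inverse of [write_sa_newick()]: leaves attached by zero-length
#' branches are folded back into degree-2 sampled-ancestor nodes. Leaf
#' ages are set from root-to-tip path lengths with the youngest sample
#' at `present`, unless an `origin_age` is given, in which case the root
#' sits at `origin_age - root_branch`.
#'
#' @param text Newick string.
#' @param origin_age optional origin age; defaults to the root age plus
#'   the root branch length if present, else the root age.
#' @return An [sa_tree].
#' @export
read_sa_newick <- function(text, origin_age = NULL) {
  s <- gsub("[[:space:]]", "", sub(";\\s*$", "", trimws(text)))
  pos <- 1L
  nchars <- nchar(s)
  peek <- function() substr(s, pos, pos)
  ## recursive-descent parse into (label, length, children) lists
  parse_clade <- function() {
    kids <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        kids[[length(kids) + 1L]] <- parse_clade()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed newick near position ", pos)
      }
    }
    m <- regmatches(substr(s, pos, nchars),
                    regexpr("^[^,:();]*", substr(s, pos, nchars)))
    label <- m
    pos <<- pos + nchar(m)
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      m <- regmatches(substr(s, pos, nchars),
                      regexpr("^[-+0-9.eE]+", substr(s, pos, nchars)))
      len <- as.numeric(m)
      pos <<- pos + nchar(m)
    }
    list(label = label, length = len, children = kids)
  }
  tree <- parse_clade()
  root_branch <- if (is.na(tree$length)) 0 else tree$length
  ## flatten with depths
  parent <- integer(0); depth <- numeric(0); label <- character(0)
  is_leaf <- logical(0)
  add <- function(node, par, d) {
    parent[length(parent) + 1L] <<- par
    depth[length(depth) + 1L] <<- d
    label[length(label) + 1L] <<- if (nzchar(node$label)) node$label else NA_character_
    is_leaf[length(is_leaf) + 1L] <<- !length(node$children)
    me <- length(parent)
    for (k in node$children) add(k, me, d + k$length)
    me
  }
  add(tree, NA_integer_, 0)
  if (!is.null(origin_age)) {
    ## anchor absolute ages at the stated origin
    age <- (origin_age - root_branch) - depth
  } else {
    age <- max(depth[is_leaf]) - depth      # youngest sample at 0
  }
  ## fold zero-length leaves into sampled-ancestor parents
  n <- length(parent)
  is_sample <- is_leaf
  drop <- rep(FALSE, n)
  for (i in which(is_leaf)) {
    p <- parent[i]
    if (!is.na(p) && abs(age[i] - age[p]) < 1e-9) {
      sibs <- setdiff(which(!is.na(parent) & parent == p), i)
      if (length(sibs) == 1L) {
        label[p] <- label[i]; is_sample[p] <- TRUE
        drop[i] <- TRUE
      }
    }
  }
  keep <- which(!drop)
  remap <- match(seq_len(n), keep)
  parent2 <- remap[parent[keep]]
  age2 <- age[keep]; lab2 <- label[keep]; samp2 <- is_sample[keep]
  r_age <- age2[is.na(parent2)]
  if (is.null(origin_age)) origin_age <- r_age + root_branch
  sa_tree(parent2, age2, samp2, lab2, origin_age)
}
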