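# Tree I/O and interrogation: newick parsing with validation, node ages,
# lineage-through-time curves, and clade age summaries across tree samples.
#
# Trees are ape `phylo` objects throughout. A "chronogram" is an ultrametric
# phylo whose branch lengths are Myr; a "phylogram" carries expected
# substitutions/site.

#' Parse a rooted newick tree with validation
#'
#' Wraps [ape::read.tree()] with the checks the downstream models rely on:
#' balanced parentheses, unique tip labels, branch lengths present and
#' nonnegative on all non-root edges, and (for chronograms) ultrametricity.
#'
#' @param x A newick string (must contain `(` and `;`) or a file path.
#' @param mode `"phylogram"` (default) or `"chronogram"`. Chronograms must
#'   have all tips at equal depth within `tol`.
#' @param tol Ultrametricity tolerance in branch-length units (default
#'   1e-6).
#' @param repair If `TRUE`, chronograms within `tol` of ultrametric have
#'   their terminal branches adjusted so tip ages are exactly 0.
#' @return A `phylo` object.
#' @export
parse_newick <- function(x, mode = c("phylogram", "chronogram"),
                         tol = 1e-6, repair = FALSE) {
  mode <- match.arg(mode)
  if (length(x) != 1 || !is.character(x)) stop("x must be a single string")
  text <- if (grepl("\\(", x) && grepl(";", x)) x else {
    if (!file.exists(x)) stop("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in newick: ", n_open, " '(' vs ",
         n_close, " ')'")
  }
  phy <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("newick parse failure near: ", substr(text, 1, 60))
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) {
    bad <- phy$edge[is.na(phy$edge.length), 2]
    bad_lab <- ifelse(bad <= ape::Ntip(phy), phy$tip.label[bad],
                      paste0("node ", bad))
    stop("missing branch length(s) above: ", paste(bad_lab, collapse = ", "))
  }
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (mode == "chronogram") {
    phy <- assert_chronogram(phy, tol = tol, repair = repair)
  }
  phy
}

#' @rdname parse_newick
#' @param phy A `phylo` object.
#' @param file Optional output path; when `NULL` the newick string is
#'   returned.
#' @param digits Number of significant digits for branch lengths.
#' @export
write_newick <- function(phy, file = NULL, digits = 10) {
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Node ages of a chronogram
#'
#' Ages in Myr before present (tips at 0), indexed by ape node number
#' (tips `1..n`, then internal nodes).
#'
#' @param phy An ultrametric `phylo`.
#' @return A numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(phy) {
  nt <- ape::Ntip(phy)
  d <- ape::node.depth.edgelength(phy)
  a <- max(d[seq_len(nt)]) - d
  a[a < 0 & a > -1e-9] <- 0
  a
}

#' Validate (and optionally repair) a chronogram
#'
#' @inheritParams parse_newick
#' @param phy A `phylo`.
#' @return The validated `phylo` (terminal branches adjusted if
#'   `repair = TRUE`).
#' @export
assert_chronogram <- function(phy, tol = 1e-6, repair = FALSE) {
  nt <- ape::Ntip(phy)
  d <- ape::node.depth.edgelength(phy)
  spread <- max(d[seq_len(nt)]) - min(d[seq_len(nt)])
  if (spread > tol) {
    stop("tree is not ultrametric: tips at unequal depth (spread ",
         format(spread, digits = 4), " > tol ", tol, ")")
  }
  if (repair && spread > 0) {
    term <- phy$edge[, 2] <= nt
    target <- max(d[seq_len(nt)])
    phy$edge.length[term] <- phy$edge.length[term] +
      (target - d[phy$edge[term, 2]])
  }
  phy
}

is_binary_tree <- function(phy) ape::is.binary.phylo(phy)

# children matrix (rows = nodes, two columns, 0 for tips); errors on
# polytomies when `strict`
children_of <- function(phy, strict = TRUE) {
  n <- ape::Ntip(phy) + phy$Nnode
  ch <- matrix(0L, n, 2)
  cnt <- integer(n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    cnt[p] <- cnt[p] + 1L
    if (cnt[p] > 2L) {
      if (strict) stop("tree contains a polytomy at node ", p,
                       "; a fully resolved (binary) tree is required")
      next
    }
    ch[p, cnt[p]] <- phy$edge[i, 2]
  }
  ch
}

# node indices in postorder (every node after its children), root last
postorder_nodes <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  root <- ape::Ntip(phy) + 1L
  c(po$edge[, 2], root)
}

# branch length above each node (NA for root), indexed by node
parent_edge_length <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  len <- rep(NA_real_, n)
  len[phy$edge[, 2]] <- phy$edge.length
  len
}

parent_of <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

#' Lineage-through-time curve
#'
#' The number of reconstructed lineages as a step function of age, under the
#' crown convention: the count is 2 at the root (crown) age and reaches the
#' number of tips at the present.
#'
#' @param phy An ultrametric `phylo` with at least 2 tips.
#' @return A tibble (class `rd_ltt`) with columns `age` (Ma, decreasing) and
#'   `lineages`; the last row is `(0, Ntip)`.
#' @export
ltt_curve <- function(phy) {
  if (ape::Ntip(phy) < 2) stop("LTT needs at least 2 tips")
  assert_chronogram(phy)
  ages <- node_ages(phy)
  nt <- ape::Ntip(phy)
  internal <- (nt + 1):(nt + phy$Nnode)
  kids <- tabulate(phy$edge[, 1], nbins = nt + phy$Nnode)
  ord <- internal[order(ages[internal], decreasing = TRUE)]
  counts <- 1 + cumsum(kids[ord] - 1)
  out <- tibble::tibble(age = c(ages[ord], 0),
                        lineages = c(counts, nt))
  class(out) <- c("rd_ltt", class(out))
  out
}

# clade key: sorted descendant tip labels, ";"-joined; indexed by node
clade_keys <- function(phy) {
  nt <- ape::Ntip(phy)
  n <- nt + phy$Nnode
  sets <- vector("list", n)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c_ <- po$edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[c_]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = ";"), character(1))
}

#' Summarize clade ages across a sample of trees
#'
#' For each internal node of a reference chronogram, matches the identical
#' clade (same descendant tip set) in every tree of a sample and summarizes
#' the matched node ages: mean, 2.5% and 97.5% quantiles, and the number of
#' sample trees containing the clade. Used to put confidence intervals from
#' a dated tree sample onto a consensus tree.
#'
#' @param reference An ultrametric `phylo`.
#' @param sample A list of ultrametric `phylo` objects with the identical
#'   tip set.
#' @return A tibble with one row per internal reference node: `node`,
#'   `clade` (sorted tip-label key), `n_tips`, `support` (trees containing
#'   the clade), `mean_age`, `age_lo`, `age_hi`, and `matched` (FALSE when
#'   the clade occurs in no sample tree; summaries are then `NA`).
#' @export
clade_ages_across_trees <- function(reference, sample) {
  ref_tips <- sort(reference$tip.label)
  for (i in seq_along(sample)) {
    st <- sort(sample[[i]]$tip.label)
    if (!identical(ref_tips, st)) {
      stop("tip-set mismatch with sample tree ", i, ": ",
           paste(c(setdiff(ref_tips, st), setdiff(st, ref_tips)),
                 collapse = ", "))
    }
  }
  nt <- ape::Ntip(reference)
  internal <- (nt + 1):(nt + reference$Nnode)
  ref_keys <- clade_keys(reference)[internal]
  ref_ages <- node_ages(reference)[internal]
  # per sample tree: named age vector keyed by clade
  maps <- lapply(sample, function(tr) {
    ni <- (ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode)
    stats::setNames(node_ages(tr)[ni], clade_keys(tr)[ni])
  })
  rows <- lapply(seq_along(internal), function(i) {
    ages <- unlist(lapply(maps, function(m) unname(m[ref_keys[i]])))
    ages <- ages[!is.na(ages)]
    k <- length(ages)
    tibble::tibble(
      node = internal[i], clade = ref_keys[i],
      n_tips = lengths(strsplit(ref_keys[i], ";", fixed = TRUE)),
      reference_age = ref_ages[i], support = k,
      mean_age = if (k > 0) mean(ages) else NA_real_,
      age_lo = if (k > 0) unname(stats::quantile(ages, 0.025)) else NA_real_,
      age_hi = if (k > 0) unname(stats::quantile(ages, 0.975)) else NA_real_,
      matched = k > 0)
  })
  dplyr::bind_rows(rows)
}
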