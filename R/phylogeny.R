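#' Build the binary character matrix for tree inference
#'
#' Encodes presence (VAF > 0) of every non-silent alteration found in at
#' least two samples. Silent and singleton rows are removed.
#'
#' @param vaf matrix (alterations x samples) of VAFs; `NA` marks cells
#'   without sufficient coverage and is propagated (unknown state).
#' @param consequence_class character vector per alteration (`"silent"`,
#'   `"non-silent"`, `"unknown"`); `"silent"` rows are dropped.
#' @param min_samples minimum number of carrying samples.
#' @return binary 0/1 matrix (alterations x samples).
#' @export
build_character_matrix <- function(vaf, consequence_class = NULL,
                                   min_samples = 2) {
  stopifnot(is.matrix(vaf))
  if (ncol(vaf) < 3) stop("at least 3 samples required for an unrooted tree")
  b <- (vaf > 0) * 1L                      # NA cells stay NA (not covered)
  keep <- rowSums(b, na.rm = TRUE) >= min_samples
  if (!is.null(consequence_class)) {
    stopifnot(length(consequence_class) == nrow(vaf))
    keep <- keep & consequence_class != "silent"
  }
  b[keep, , drop = FALSE]
}

.as_phydat <- function(mat) {
  ## taxa as rows for phangorn; NA cells become the ambiguous state "?"
  m <- t(mat)
  storage.mode(m) <- "character"
  m[is.na(m)] <- "?"
  contrast <- matrix(c(1, 0,
                       0, 1,
                       1, 1), 3, 2, byrow = TRUE,
                     dimnames = list(c("0", "1", "?"), c("0", "1")))
  phangorn::phyDat(m, type = "USER", contrast = contrast)
}

#' Parsimony score of a tree for a binary character matrix
#'
#' Fitch length: the minimal total number of state changes needed to explain
#' every character on the given topology.
#'
#' @param tree a `phylo` whose tip labels are the matrix column names.
#' @param mat binary matrix from [build_character_matrix()].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, mat) {
  stopifnot(setequal(tree$tip.label, colnames(mat)))
  as.integer(phangorn::fitch(tree, .as_phydat(mat)))
}

#' Maximum-parsimony tree search by the parsimony ratchet
#'
#' Searches unrooted tree space with the parsimony ratchet (alternating
#' hill-climbing under perturbed character weights and under the original
#' weights). When several co-optimal trees are found, the one with the
#' lexicographically smallest Newick string is returned; all co-optimal
#' trees are kept in the result. Deterministic given `seed`.
#'
#' @param mat binary matrix (alterations x samples).
#' @param iterations maximum ratchet iterations.
#' @param seed integer seed.
#' @param outgroup optional name of an all-zero pseudo-germline taxon
#'   appended to the matrix before the search (used later for rooting);
#'   `NULL` to search over the samples alone.
#' @return list of class `ctc_phylo`: `tree` (unrooted `phylo`), `score`,
#'   `all_trees` (`multiPhylo` of co-optimal trees), `matrix`.
#' @export
parsimony_ratchet <- function(mat, iterations = 200, seed = 1,
                              outgroup = "germline") {
  stopifnot(is.matrix(mat))
  if (iterations < 1) stop("iterations must be >= 1")
  if (ncol(mat) < 4) stop("at least 4 samples required for tree search")
  if (!is.null(outgroup)) {
    if (outgroup %in% colnames(mat))
      stop("outgroup name collides with a sample")
    mat <- cbind(mat, setNames(rep(0L, nrow(mat)), outgroup))
    colnames(mat)[ncol(mat)] <- outgroup
  }
  dat <- .as_phydat(mat)
  set.seed(seed)
  best <- phangorn::pratchet(dat, maxit = iterations, minit = 10, k = 10,
                             trace = 0, all = TRUE)
  trees <- if (inherits(best, "multiPhylo")) best else c(best)
  nwk <- vapply(trees, function(t) {
    ape::write.tree(ape::ladderize(ape::unroot(t)))
  }, character(1))
  o <- order(nwk)
  tree <- ape::unroot(trees[[o[1L]]])
  structure(list(tree = tree,
                 score = as.integer(phangorn::fitch(tree, dat)),
                 all_trees = trees, matrix = mat, outgroup = outgroup),
            class = "ctc_phylo")
}

#' Assign alterations to tree branches
#'
#' Roots the tree at the pseudo-germline outgroup and assigns each matrix
#' row (and, optionally, each copy-number aberration) to the branch whose
#' downstream leaf set equals the alteration's presence set. Cells marked
#' `NA` (not covered) carry no information: the alteration is then mapped to
#' the smallest clade that contains every known-present sample and no
#' known-absent one, which reduces to the exact-equality rule when all cells
#' are observed. Alterations compatible with no clade are flagged
#' homoplastic. Mutation and CNA counts are reported separately per branch.
#'
#' @param phylo a `ctc_phylo` from [parsimony_ratchet()] (searched with an
#'   outgroup), or a rooted `phylo`.
#' @param mat binary SNV matrix (alterations x samples), `NA` = not covered.
#' @param cna_mat optional binary CNA matrix (aberrations x samples).
#' @return list with `tree` (rooted `phylo`), `branches` (data.frame per
#'   edge: child node, downstream leaves, `n_snvs`, `n_cnas`), `assignment`
#'   (per alteration: edge or `NA`), `homoplastic` (alteration ids).
#' @export
assign_branch_alterations <- function(phylo, mat, cna_mat = NULL) {
  if (inherits(phylo, "ctc_phylo")) {
    tree <- phylo$tree
    og <- phylo$outgroup
    stopifnot(!is.null(og))
    tree <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  } else {
    tree <- phylo
    og <- NULL
  }
  ntip <- length(tree$tip.label)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  ## accumulate descendants bottom-up over edges in postorder
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[child]])
  }
  edge_sets <- lapply(seq_len(nrow(tree$edge)), function(e) {
    setdiff(sort(unlist(desc[[tree$edge[e, 2L]]])), og)
  })
  edge_key <- vapply(edge_sets, paste, character(1), collapse = "|")

  edge_size <- lengths(edge_sets)
  assign_rows <- function(m) {
    if (is.null(m) || !nrow(m)) {
      return(data.frame(alteration = character(), edge = integer(),
                        stringsAsFactors = FALSE))
    }
    edge <- vapply(seq_len(nrow(m)), function(k) {
      r <- m[k, ]
      pres <- intersect(colnames(m)[!is.na(r) & r > 0], tree$tip.label)
      abst <- intersect(colnames(m)[!is.na(r) & r == 0], tree$tip.label)
      if (!length(pres)) return(NA_integer_)
      ok <- vapply(edge_sets, function(s) {
        all(pres %in% s) && !any(abst %in% s)
      }, logical(1))
      if (!any(ok)) return(NA_integer_)
      cand <- which(ok)
      cand[which.min(edge_size[cand])]
    }, integer(1))
    data.frame(alteration = rownames(m), edge = edge,
               stringsAsFactors = FALSE)
  }
  snv <- assign_rows(mat)
  cna <- assign_rows(cna_mat)
  branches <- data.frame(
    edge = seq_len(nrow(tree$edge)),
    child = tree$edge[, 2L],
    leaves = edge_key,
    n_snvs = vapply(seq_len(nrow(tree$edge)),
                    function(e) sum(snv$edge == e, na.rm = TRUE), integer(1)),
    n_cnas = vapply(seq_len(nrow(tree$edge)),
                    function(e) sum(cna$edge == e, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  assignment <- rbind(
    if (nrow(snv)) cbind(snv, type = "snv"),
    if (nrow(cna)) cbind(cna, type = "cna"))
  list(tree = tree, branches = branches, assignment = assignment,
       homoplastic = assignment$alteration[is.na(assignment$edge)])
}

#' Unrooted bipartitions of a tree
#'
#' Convenience accessor returning each internal edge's tip-label split, used
#' to compare a recovered topology with a ground-truth clade structure.
#'
#' @param tree a `phylo`.
#' @param drop tips to ignore (e.g. the pseudo-germline outgroup).
#' @return list of character vectors (one side of each non-trivial split,
#'   the side not containing the first remaining tip).
#' @export
tree_bipartitions <- function(tree, drop = "germline") {
  tree <- ape::unroot(ape::drop.tip(tree, intersect(drop, tree$tip.label)))
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- lapply(parts, function(p) sort(labs[p]))
  out <- out[vapply(out, function(s) {
    length(s) >= 2 && length(s) <= length(tips) - 2
  }, logical(1))]
  ## canonical side: the one not containing the alphabetically first tip
  out <- lapply(out, function(s) {
    if (tips[1L] %in% s) sort(setdiff(tips, s)) else s
  })
  unique(out)
}

#' Does a tree contain a given unrooted split?
#'
#' @param tree a `phylo`.
#' @param tips character vector forming one side of the candidate split.
#' @param drop tips ignored before the comparison.
#' @return logical.
#' @export
has_clade <- function(tree, tips, drop = "germline") {
  all_tips <- sort(setdiff(tree$tip.label, drop))
  side <- sort(tips)
  if (all_tips[1L] %in% side) side <- sort(setdiff(all_tips, side))
  any(vapply(tree_bipartitions(tree, drop), identical, logical(1), side))
}
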