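# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written as straight-line re-statements, separate from the
# package's code paths.

## ---- somatic-filter oracle ---------------------------------------------

# Rule-by-rule re-statement of the somatic post-filters, evaluated per row
# with explicit if/else logic (no shared code with apply_somatic_filters).
oracle_filter_one <- function(row, policy) {
  if (isTRUE(row$caller_blacklist)) return(FALSE)
  if (!(row$filter_flag %in% policy$accepted_flags)) return(FALSE)
  if (row$depth < policy$min_depth) return(FALSE)
  if (row$normal_depth < policy$min_depth) return(FALSE)
  if (row$qss < policy$min_qss) return(FALSE)
  if (row$depth == 0) return(FALSE)
  if (row$alt_count / row$depth < policy$min_vaft) return(FALSE)
  if (row$alt_count < policy$min_alt_reads) return(FALSE)
  if (row$normal_depth > 0 &&
      row$normal_alt / row$normal_depth > policy$max_vafn) return(FALSE)
  TRUE
}

random_candidates <- function(n, seed) {
  set.seed(seed)
  depth <- sample(0:100, n, replace = TRUE)
  normal_depth <- sample(0:100, n, replace = TRUE)
  data.frame(
    variant_id = paste0("v", seq_len(n)),
    sample_id = "S",
    depth = depth,
    alt_count = vapply(depth, function(d) sample(0:d, 1), integer(1)),
    filter_flag = sample(c("PASS", "t_lod_fstar", "clustered_events",
                           "germline_risk"), n, replace = TRUE),
    qss = sample(0:60, n, replace = TRUE),
    caller_blacklist = runif(n) < 0.05,
    normal_depth = normal_depth,
    normal_alt = vapply(normal_depth, function(d) {
      if (runif(1) < 0.7) 0L else sample(0:min(d, 3), 1)
    }, integer(1)),
    stringsAsFactors = FALSE)
}

## ---- exact Fisher enumeration oracle -----------------------------------

# Two-sided Fisher p for a 2x2 table [[a, b], [c, d]] by direct
# hypergeometric enumeration of all tables with the observed margins:
# conditioning on margins, P(top-left = x) = dhyper(x, a+c, b+d, a+b), and
# the two-sided p sums all tables no more probable than the observed one
# (with the conventional 1e-7 relative tie tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0L, k - n)
  hi <- min(m, k)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- pr[match(a, x)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

## ---- independent Fitch score -------------------------------------------

# Bottom-up set-based Fitch count for binary characters (NA = {0,1}),
# evaluated on an arbitrary rooting of the tree.
oracle_fitch <- function(tree, mat) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  score <- 0L
  for (ch in seq_len(nrow(mat))) {
    states <- vector("list", max(tr$edge))
    for (i in seq_len(ntip)) {
      v <- mat[ch, tr$tip.label[i]]
      states[[i]] <- if (is.na(v)) c(0L, 1L) else as.integer(v)
    }
    kids <- split(tr$edge[, 2L], tr$edge[, 1L])
    todo <- as.integer(names(kids))
    while (length(todo)) {
      progressed <- FALSE
      for (node in todo) {
        cs <- kids[[as.character(node)]]
        if (any(vapply(cs, function(c) is.null(states[[c]]), logical(1))))
          next
        s <- states[[cs[1L]]]
        for (c in cs[-1L]) {
          i2 <- intersect(s, states[[c]])
          if (length(i2)) s <- i2
          else { s <- union(s, states[[c]]); score <- score + 1L }
        }
        states[[node]] <- s
        todo <- setdiff(todo, node)
        progressed <- TRUE
      }
      if (!progressed) stop("cyclic tree?")
    }
  }
  score
}

# Exhaustive minimum parsimony score over all unrooted topologies.
oracle_exhaustive_best <- function(mat) {
  trees <- phangorn::allTrees(ncol(mat), rooted = FALSE,
                              tip.label = colnames(mat))
  min(vapply(trees, oracle_fitch, integer(1), mat = mat))
}

random_binary_matrix <- function(n_char, n_taxa, seed, p = 0.4) {
  set.seed(seed)
  matrix(rbinom(n_char * n_taxa, 1, p), n_char, n_taxa,
         dimnames = list(paste0("v", seq_len(n_char)),
                         paste0("s", seq_len(n_taxa))))
}

## ---- shared cohort fixtures (memoized) ---------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Reduced genome for unit tests: same per-sample structure, fewer chromosomes.
small_config <- function(seed = 5, ...) {
  sim_config(chrom_mb = stats::setNames(rep(100, 8), paste0("chr", 1:8)),
             n_cnas = 8, target_size_mb = 12, seed = seed, ...)
}

small_cohort <- function() cached("small_cohort", simulate_cohort(small_config()))

default_cohort <- function() cached("default_cohort",
                                    simulate_cohort(sim_config(seed = 101)))

default_pipeline <- function() cached("default_pipeline",
                                      run_pipeline(default_cohort()))
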