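# Shared fixtures, built in code at test time.

# small specimen data frame: one row per individual
make_specimen_df <- function(species, site = "S1", trap = "T1",
                             date = "2015-06-15") {
  n <- max(length(species), length(site), length(trap), length(date))
  data.frame(
    specimen_id = sprintf("x%03d", seq_len(n)),
    species = rep_len(species, n),
    site_id = rep_len(site, n),
    trap_id = rep_len(trap, n),
    date = rep_len(date, n),
    stringsAsFactors = FALSE
  )
}

write_specimen_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# down-scaled simulation config: same stated world, smaller community,
# so the default test run stays fast
small_sim_config <- function(seed = 42, ...) {
  sim_config(n_species = 40, n_genera = 12, n_families = 3,
             total_individuals = 6000, seed = seed, ...)
}

# memoized default small dataset shared across test files
sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_sim_config())
    cache
  }
})

# independent brute-force patristic distances: breadth-first path sums over
# the edge list (no ape path machinery)
brute_force_cophenetic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(n_tip)) {
    dist_to <- rep(NA_real_, n_node)
    dist_to[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        nb <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(dist_to[nb])) {
          dist_to[nb] <- dist_to[v] + w
          queue <- c(queue, nb)
        }
      }
    }
    d[start, ] <- dist_to[seq_len(n_tip)]
  }
  d
}

tip_depths <- function(tree) {
  ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
}
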