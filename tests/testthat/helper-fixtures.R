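# Shared fixtures and independent oracles used across test files.

# Molecular parameters of the solute (trisodium fructose 1,6-diphosphate
# free-acid formula), with an assumed crystal density of 1.6 g/cm^3 for
# tests that need a molecular volume.
fdp_mol <- function() {
  molecular_params(formula = c(C = 6, H = 14, O = 12, P = 2), density = 1.6)
}

# Independent single-linkage clustering oracle: O(n^2) adjacency under
# minimum-image distances, components by breadth-first search. Shares no
# code with cluster_by_cutoff (which uses union-find).
brute_cluster <- function(frame, species, cutoff) {
  sel <- which(frame$species == species)
  n <- length(sel)
  if (n == 0) return(list(particle_index = integer(0), cluster_id = integer(0)))
  pos <- frame$positions[sel, , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pos[i, ] - pos[j, ]
      d <- d - frame$box * round(d / frame$box)
      adj[i, j] <- sqrt(sum(d^2)) <= cutoff
    }
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    next_id <- next_id + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- next_id
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  list(particle_index = sel, cluster_id = comp)
}

# Two partitions are the same up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# A random wrapped frame with two species, n <= 50 particles.
random_frame <- function(seed, n = 30, box = c(4, 4, 4)) {
  set.seed(seed)
  particle_frame(
    positions = cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                      runif(n, 0, box[3])),
    species = sample(c("solute", "water"), n, replace = TRUE),
    box = box
  )
}
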