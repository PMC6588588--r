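# shared fixtures, built in code

# Th1-like toy pathway: one ligand-to-TF chain plus the process node
toy_pathway <- function(inhibit = FALSE) {
  pathway(
    nodes = data.frame(
      id = c("IFNG", "IFNGR1", "STAT1", "TBX21", "Th1_diff"),
      role = c("ligand", "receptor", "kinase", "tf", "process")),
    edges = data.frame(
      src = c("IFNG", "IFNGR1", "STAT1", "TBX21"),
      dst = c("IFNGR1", "STAT1", "TBX21", "Th1_diff"),
      sign = c(1, if (inhibit) -1 else 1, 1, 1)),
    routes = list(r1 = c("IFNG", "IFNGR1", "STAT1", "TBX21")),
    name = "th1_toy", tf = "TBX21")
}

# random small DAG with node k -> only nodes of larger index; last node is
# the TF, a process node dangles off it
random_dag_pathway <- function(n_nodes = 6, p_edge = 0.5) {
  ids <- LETTERS[seq_len(n_nodes)]
  tf <- ids[n_nodes]
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (runif(1) < p_edge) {
        edges[[length(edges) + 1]] <- data.frame(
          src = ids[i], dst = ids[j], sign = sample(c(-1, 1), 1))
      }
    }
  }
  if (length(edges) == 0) {
    edges[[1]] <- data.frame(src = ids[1], dst = tf, sign = 1)
  }
  edges <- do.call(rbind, edges)
  edges <- rbind(edges, data.frame(src = tf, dst = "ZPROC", sign = 1))
  pathway(nodes = data.frame(id = c(ids, "ZPROC"),
                             role = c(rep("kinase", n_nodes - 1), "tf",
                                      "process")),
          edges = edges, name = "dag", tf = tf)
}

# independent brute-force enumeration of simple source->tf paths
brute_force_paths <- function(p) {
  e <- p$edges[p$edges$src != p$process & p$edges$dst != p$process, ]
  nodes <- unique(c(e$src, e$dst, p$tf))
  sources <- setdiff(nodes, e$dst)
  out <- list()
  grow <- function(path) {
    last <- path[length(path)]
    if (last == p$tf) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nxt in e$dst[e$src == last]) {
      if (!nxt %in% path) grow(c(path, nxt))
    }
  }
  for (s in sources) grow(s)
  out
}

# product of edge signs along a path, by direct lookup
brute_force_net_sign <- function(p, path, from_idx) {
  s <- 1
  for (i in seq(from_idx, length(path) - 1)) {
    hit <- p$edges$src == path[i] & p$edges$dst == path[i + 1]
    s <- s * p$edges$sign[hit]
  }
  s
}

# tiny deterministic cohort around the toy pathway for scoring tests
toy_cohort <- function(n_subjects = 8) {
  genes <- c("IFNG", "IFNGR1", "STAT1", "TBX21", "X1", "X2")
  set.seed(42)
  m <- matrix(rnorm(length(genes) * n_subjects), nrow = length(genes),
              dimnames = list(genes, sprintf("P%02d", seq_len(n_subjects))))
  m
}

# frozen two-group survival fixture; oracle values computed once with an
# independent survival library (lifelines) and hardcoded in tests
survival_fixture <- function() {
  list(
    time = c(5, 8, 12, 14, 20, 21, 25, 30, 33, 40,
             3, 6, 7, 9, 11, 13, 16, 18, 22, 28),
    event = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1,
              1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
    group2 = rep(c("a", "b"), each = 10),
    group4 = rep(c("a", "b", "c", "d"), each = 5),
    ids = sprintf("S%02d", 1:20)
  )
}

clinical_from_fixture <- function(fx) {
  tibble::tibble(subject_id = fx$ids, time_days = fx$time, event = fx$event)
}
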