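#' Configuration for the synthetic cohort generator
#'
#' The generator emulates a tumor-cohort transcriptome of log2
#' tumor/control ratios with a planted TF-driven regulatory structure.
#' Subjects come in three states: *activated* (upstream route genes and the
#' TF shifted coherently), *suppressed* (upstream input present but the TF
#' mirrored, i.e. decoupled at the TF - the configuration the R score
#' flags as negative) and *neutral* (pathway disengaged). Planted Up/Down
#' targets track the TF with coupling 1 in activated subjects, a reduced
#' coupling in suppressed subjects (partial loss of TF-driven regulation)
#' and 0 in neutral subjects; the coupling coefficient is solved from the
#' mixture moments so the realized Pearson correlation with the TF over
#' responsive subjects matches `target_corr_up` / `target_corr_down`.
#' Survival is exponential with log-hazard
#' `-survival_link * s_k`, where `s_k` is the subject's realized consistency
#' of the planted targets with the TF (the ground-truth analogue of M),
#' plus uniform thinning to a `censor_rate` fraction of censored records.
#'
#' @param n_subjects,n_genes Cohort size and total gene count.
#' @param n_routes,route_length Number of upstream routes and genes per
#'   route (TF excluded).
#' @param fraction_activated,fraction_suppressed State fractions (sum <= 1).
#' @param n_up_planted,n_down_planted Planted target counts.
#' @param target_corr_up,target_corr_down Intended TF correlations over
#'   responsive subjects (|corr| < 1).
#' @param noise_sd Gaussian noise SD on the log2-ratio scale.
#' @param shift Regulatory shift of route genes / TF in responsive
#'   subjects (log2 units).
#' @param suppressed_coupling Target-TF coupling retained in suppressed
#'   subjects, in [0, 1].
#' @param n_decoy_candidates Unregulated genes mixed into the candidate
#'   set (PTG) alongside the planted targets.
#' @param survival_link Log-hazard decrease per unit of true downstream
#'   consistency.
#' @param base_hazard Baseline hazard per day (default: median survival
#'   3 years at consistency 0).
#' @param censor_rate Expected fraction of censored subjects, in [0, 1].
#' @param stage_count Number of clinical stages (1 = no stage column);
#'   stages are assigned by hazard quantiles.
#' @param seed Integer seed; every draw flows through it.
#' @return A validated `pd_sim_config` list.
#' @export
simulation_config <- function(n_subjects = 300, n_genes = 1000,
                              n_routes = 2, route_length = 4,
                              fraction_activated = 0.15,
                              fraction_suppressed = 0.15,
                              n_up_planted = 30, n_down_planted = 30,
                              target_corr_up = 0.7,
                              target_corr_down = -0.6,
                              noise_sd = 1, shift = 2,
                              suppressed_coupling = 0.5,
                              n_decoy_candidates = 40,
                              survival_link = 2,
                              base_hazard = log(2) / 1095,
                              censor_rate = 0.3, stage_count = 1,
                              seed = 1) {
  cfg <- as.list(environment())
  if (fraction_activated < 0 || fraction_suppressed < 0 ||
      fraction_activated + fraction_suppressed > 1) {
    pd_abort("state fractions must be in [0,1] and sum to <= 1",
             "pd_config_error")
  }
  if (abs(target_corr_up) >= 1 || abs(target_corr_down) >= 1) {
    pd_abort("target correlations must satisfy |corr| < 1",
             "pd_config_error")
  }
  n_pathway <- n_routes * route_length + 1
  if (n_up_planted + n_down_planted + n_decoy_candidates >
      n_genes - n_pathway) {
    pd_abort("planted + decoy candidate counts exceed n_genes - pathway size",
             "pd_config_error")
  }
  check_threshold(censor_rate, "censor_rate", lo = 0, hi = 1)
  check_threshold(suppressed_coupling, "suppressed_coupling", lo = 0, hi = 1)
  if (noise_sd <= 0 || shift <= 0 || n_subjects < 10) {
    pd_abort("need noise_sd > 0, shift > 0, n_subjects >= 10",
             "pd_config_error")
  }
  structure(cfg, class = "pd_sim_config")
}

# solve the coupling coefficient a such that corr(target, TF) over the
# responsive mixture equals rho, given the two-group coupling kappa
solve_coupling <- function(rho, shift, noise_sd, w_act, kappa) {
  if (rho == 0) return(0)
  s2 <- shift^2 + noise_sd^2            # E[t^2 | group]
  mu <- shift * (2 * w_act - 1)         # E[t] over responsive
  var_t <- s2 - mu^2
  corr_of <- function(a) {
    e_tx <- a * s2 * (w_act + (1 - w_act) * kappa)
    e_x <- a * shift * (w_act - (1 - w_act) * kappa)
    e_x2 <- a^2 * s2 * (w_act + (1 - w_act) * kappa^2) + noise_sd^2
    (e_tx - mu * e_x) / sqrt(var_t * (e_x2 - e_x^2))
  }
  f <- function(a) corr_of(a) - abs(rho)
  if (f(1e4) < 0) {
    pd_abort(sprintf("target correlation %.2f infeasible for this design",
                     rho), "pd_config_error")
  }
  a <- stats::uniroot(f, c(1e-8, 1e4), tol = 1e-10)$root
  sign(rho) * a
}

#' Simulate a cohort with planted regulatory ground truth
#'
#' See [simulation_config()] for the generative model. Byte-identical
#' output for identical configs (the seed covers every draw).
#'
#' @param config A `pd_sim_config`.
#' @return A `pd_synthetic_cohort` list: `expr` (wide tibble, `gene` +
#'   one column per subject), `clinical`, `pathway` (routes declared),
#'   `planted_up`, `planted_down`, `ptg` (a `pd_gene_set`, planted targets
#'   plus decoy candidates), `truth` (tibble `subject_id`, `state`,
#'   `true_score`) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "pd_sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_subjects
  subjects <- sprintf("S%04d", seq_len(n))
  n_act <- round(cfg$fraction_activated * n)
  n_sup <- round(cfg$fraction_suppressed * n)
  state <- sample(c(rep("activated", n_act), rep("suppressed", n_sup),
                    rep("neutral", n - n_act - n_sup)))
  z <- ifelse(state == "activated", 1, ifelse(state == "suppressed", -1, 0))
  responsive <- state != "neutral"

  # pathway skeleton: n_routes chains of route_length genes into the TF;
  # the second route carries one inhibitory edge so net signs mix
  tf <- "TF1"
  route_genes <- map(seq_len(cfg$n_routes), function(j)
    sprintf("RT%d_%d", j, seq_len(cfg$route_length)))
  nodes <- tibble(
    id = c(unlist(route_genes), tf, "PROC"),
    role = c(map_chr(unlist(route_genes), function(g) "kinase"), "tf",
             "process"))
  nodes$role[match(map_chr(route_genes, 1), nodes$id)] <- "ligand"
  edges <- bind_rows(map(seq_len(cfg$n_routes), function(j) {
    g <- c(route_genes[[j]], tf)
    sgn <- rep(1, length(g) - 1)
    if (j %% 2 == 0 && length(sgn) >= 2) sgn[length(sgn) - 1] <- -1
    tibble(src = g[-length(g)], dst = g[-1], sign = sgn)
  }))
  edges <- bind_rows(edges, tibble(src = tf, dst = "PROC", sign = 1))
  routes <- setNames(map(route_genes, function(g) c(g, tf)),
                     paste0("route_", seq_len(cfg$n_routes)))
  pw <- pathway(nodes = nodes, edges = edges, routes = routes,
                name = "planted_pathway", tf = tf)

  noise <- function(nr) matrix(rnorm(nr * n, 0, cfg$noise_sd), nrow = nr)

  # TF and upstream route genes: upstream input is on in every responsive
  # subject; the TF mirrors the state (suppressed = TF decoupled downwards)
  tf_val <- cfg$shift * z + rnorm(n, 0, cfg$noise_sd)
  rt <- route_gene_table(pw)
  route_mat <- matrix(rnorm(nrow(rt) * n, 0, cfg$noise_sd), nrow = nrow(rt))
  route_mat <- route_mat +
    rt$net_sign %o% (cfg$shift * as.numeric(responsive))
  rownames(route_mat) <- rt$gene

  # planted targets: kappa-weighted coupling to the TF value
  w_act <- if (n_act + n_sup > 0) n_act / (n_act + n_sup) else 0.5
  kappa <- ifelse(state == "activated", 1,
                  ifelse(state == "suppressed", cfg$suppressed_coupling, 0))
  a_up <- solve_coupling(cfg$target_corr_up, cfg$shift, cfg$noise_sd,
                         w_act, cfg$suppressed_coupling)
  a_dn <- solve_coupling(cfg$target_corr_down, cfg$shift, cfg$noise_sd,
                         w_act, cfg$suppressed_coupling)
  up_genes <- sprintf("UP%03d", seq_len(cfg$n_up_planted))
  dn_genes <- sprintf("DN%03d", seq_len(cfg$n_down_planted))
  up_mat <- noise(cfg$n_up_planted) +
    rep(1, cfg$n_up_planted) %o% (a_up * kappa * tf_val)
  dn_mat <- noise(cfg$n_down_planted) +
    rep(1, cfg$n_down_planted) %o% (a_dn * kappa * tf_val)
  rownames(up_mat) <- up_genes
  rownames(dn_mat) <- dn_genes

  n_other <- cfg$n_genes - nrow(rt) - 1 - cfg$n_up_planted -
    cfg$n_down_planted
  other_genes <- sprintf("G%05d", seq_len(n_other))
  other_mat <- noise(n_other)
  rownames(other_mat) <- other_genes

  m <- rbind(matrix(tf_val, nrow = 1, dimnames = list(pw$tf)),
             route_mat, up_mat, dn_mat, other_mat)
  colnames(m) <- subjects

  # ground truth downstream consistency: realized sign-agreement of the
  # planted targets with the TF (Up with, Down against)
  v_up <- .sgn(up_mat) * rep(.sgn(tf_val), each = nrow(up_mat))
  v_dn <- -.sgn(dn_mat) * rep(.sgn(tf_val), each = nrow(dn_mat))
  true_score <- (colSums(v_up) + colSums(v_dn)) /
    (nrow(up_mat) + nrow(dn_mat))

  hazard <- cfg$base_hazard * exp(-cfg$survival_link * true_score)
  event_time <- rexp(n, rate = hazard)
  censored <- rbinom(n, 1, cfg$censor_rate) == 1
  time_obs <- ifelse(censored, event_time * runif(n), event_time)
  clinical <- tibble(subject_id = subjects,
                     time_days = pmax(round(time_obs, 1), 0.5),
                     event = as.integer(!censored))
  if (cfg$stage_count > 1) {
    qs <- quantile(hazard, probs = seq(0, 1, length.out = cfg$stage_count + 1))
    qs[1] <- -Inf; qs[length(qs)] <- Inf
    clinical$stage <- as.character(as.roman(
      cut(hazard, breaks = qs, labels = FALSE)))
  }

  ptg <- gene_set(c(up_genes, dn_genes,
                    sample(other_genes, cfg$n_decoy_candidates)),
                  provenance = "ptg",
                  parameters = list(source = "synthetic"))

  structure(list(expr = expr_as_tibble(m), clinical = clinical,
                 pathway = pw, planted_up = up_genes,
                 planted_down = dn_genes, ptg = ptg,
                 truth = tibble(subject_id = subjects, state = state,
                                true_score = true_score),
                 config = cfg),
            class = "pd_synthetic_cohort")
}

#' @export
print.pd_synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic cohort> %d subjects x %d genes (seed %d)\n",
              x$config$n_subjects, x$config$n_genes, x$config$seed))
  print(table(x$truth$state))
  invisible(x)
}

#' Deterministic TSS table for synthetic genes
#'
#' Places genes 100 kb apart on one synthetic chromosome, alternating
#' strands, giving the peak-mapping stage a toy genome to work against.
#'
#' @param genes Character vector of gene symbols.
#' @param chrom Chromosome name.
#' @param spacing Distance between consecutive TSSs (bp).
#' @return A TSS tibble as from [read_tss()].
#' @export
synthetic_tss <- function(genes, chrom = "chrS", spacing = 1e5) {
  n <- length(genes)
  tibble(gene = genes, chrom = chrom,
         tss = as.integer(seq_len(n) * spacing),
         strand = rep(c("+", "-"), length.out = n))
}

#' Simulate conservative/optimal ChIP-seq peak files
#'
#' Writes two narrowPeak files: both contain one peak whose midpoint lies
#' in the strand-aware upstream window of every bound gene, plus decoy
#' peaks placed outside all gene windows; the optimal file additionally
#' covers some unbound genes, so the conservative/optimal intersection
#' maps back to exactly the bound set.
#'
#' @param tss TSS tibble (e.g. [synthetic_tss()]).
#' @param bound_genes Genes to plant peaks for (subset of `tss$gene`).
#' @param window Window width in bp (matching the mapping window).
#' @param decoy_peaks Number of out-of-window peaks per file.
#' @param n_extra_optimal Unbound genes additionally covered in the
#'   optimal file.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Named list with paths `conservative` and `optimal`.
#' @export
simulate_peak_fixture <- function(tss, bound_genes, window = 2000,
                                  decoy_peaks = 5, n_extra_optimal = 2,
                                  seed = 1, dir = tempdir()) {
  if (!all(bound_genes %in% tss$gene)) {
    pd_abort("bound_genes must be a subset of the TSS genes",
             "pd_input_error")
  }
  withr::with_seed(seed, {
    peak_for <- function(genes) {
      rec <- tss[match(genes, tss$gene), ]
      off <- sample(seq_len(window), nrow(rec), replace = TRUE)
      mid <- ifelse(rec$strand == "+", rec$tss - off, rec$tss + off)
      tibble(chrom = rec$chrom, start = pmax(mid - 100, 0), end = mid + 100)
    }
    far <- max(tss$tss) + 10 * window
    decoys <- tibble(chrom = tss$chrom[1],
                     start = far + seq_len(decoy_peaks) * 5L * window,
                     end = far + seq_len(decoy_peaks) * 5L * window + 200L)
    if (any(decoys$start <= max(tss$tss) + window)) {
      pd_abort("cannot place decoy peaks outside all gene windows",
               "pd_input_error")
    }
    unbound <- setdiff(tss$gene, bound_genes)
    extra <- utils::head(unbound, n_extra_optimal)
    cons <- bind_rows(peak_for(bound_genes), decoys)
    opt <- bind_rows(peak_for(bound_genes), peak_for(extra), decoys)
    write_np <- function(p, path) {
      p <- mutate(p, name = sprintf("peak%d", dplyr::row_number()),
                  score = 0L, strand = ".", signal = round(runif(n(), 1, 10), 2),
                  pval = -1, qval = -1, summit = -1)
      readr::write_tsv(p, path, col_names = FALSE)
      path
    }
    paths <- list(
      conservative = write_np(cons, file.path(dir, "conservative.narrowPeak")),
      optimal = write_np(opt, file.path(dir, "optimal.narrowPeak")))
    paths
  })
}
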