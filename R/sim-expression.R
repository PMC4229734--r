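# Synthetic expression matrices with planted specificity classes.
#
# Abundance model: each gene's maximal abundance is log10-uniform over the
# configured dynamic range; the within-gene condition profile is a Dirichlet
# draw shaped per planted class so that the Es-scale classification of the
# generated matrix is guaranteed to match the planted labels:
#   specific    - one concentrated home component above the Es cutoff;
#   ubiquitous  - near-uniform mixed with a hard uniform floor, so every
#                 condition clears the ubiquity floor;
#   NUNS        - a random subset of conditions zeroed, remainder flattened
#                 below the specific cutoff.

dirichlet_rows <- function(nrow, ncol, alpha) {
  m <- matrix(rgamma(nrow * ncol, shape = alpha), nrow = nrow)
  m / rowSums(m)
}

# Flatten a probability vector until its maximum is below `cap` by repeatedly
# mixing toward the uniform distribution. Terminates whenever 1/length < cap.
flatten_below <- function(p, cap) {
  u <- 1 / length(p)
  while (max(p) >= cap) {
    p <- 0.5 * p + 0.5 * u
  }
  p
}

class_counts <- function(n_genes, proportions) {
  counts <- floor(n_genes * proportions)
  # largest-remainder apportionment of the leftover genes
  rem <- n_genes * proportions - counts
  short <- n_genes - sum(counts)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  setNames(as.integer(counts), c("ubiquitous", "NUNS", "specific"))
}

#' Simulate a gene-by-condition expression matrix with planted classes
#'
#' Generates an abundance table whose genes fall into three planted
#' specificity classes (ubiquitous / NUNS / specific) under the Es-scale
#' classification rules of the chosen regime: tissue (specific when Es >= 0.8
#' in some condition; ubiquitous when abundance is non-zero everywhere) or
#' stage (specific when Es >= 0.19; ubiquitous when Es > 0.005 everywhere).
#'
#' @param config A [sim_config()].
#' @param mode `"tissue"` or `"stage"`; selects the condition count and the
#'   classification regime the planted classes are guaranteed under.
#' @return A list with `expression` (wide tibble: `gene` column plus one
#'   numeric column per condition) and `truth` (tibble `gene`, `class`,
#'   `condition`; `condition` is the planted home condition for specific
#'   genes, `NA` otherwise).
#' @examples
#' sim <- simulate_expression_matrix(sim_config(n_genes = 100, seed = 1))
#' dplyr::count(sim$truth, class)
#' @export
simulate_expression_matrix <- function(config,
                                       mode = c("tissue", "stage")) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  n_cond <- if (mode == "tissue") config$tissue_conditions else config$stage_conditions
  cutoff <- if (mode == "tissue") 0.8 else 0.19
  conditions <- sprintf("%s_%02d", mode, seq_len(n_cond))

  with_seed(config$seed, {
    counts <- class_counts(config$n_genes, config$class_proportions)
    classes <- sample(rep(names(counts), counts))
    genes <- sprintf("g%05d", seq_len(config$n_genes))

    prof <- matrix(0, nrow = config$n_genes, ncol = n_cond)
    home <- rep(NA_character_, config$n_genes)

    idx_u <- which(classes == "ubiquitous")
    if (length(idx_u)) {
      base <- dirichlet_rows(length(idx_u), n_cond, alpha = 10)
      p <- 0.5 * base + 0.5 / n_cond
      # guard against a (vanishingly rare) heavy draw breaching the cutoff
      over <- which(apply(p, 1, max) >= 0.9 * cutoff)
      for (i in over) p[i, ] <- flatten_below(p[i, ], 0.9 * cutoff)
      prof[idx_u, ] <- p
    }

    idx_s <- which(classes == "specific")
    if (length(idx_s)) {
      ns <- length(idx_s)
      home_col <- sample.int(n_cond, ns, replace = TRUE)
      share <- if (mode == "tissue") runif(ns, 0.82, 0.98) else runif(ns, 0.25, 0.60)
      rest <- dirichlet_rows(ns, n_cond - 1L, alpha = 5) * (1 - share)
      for (i in seq_len(ns)) {
        row <- numeric(n_cond)
        row[-home_col[i]] <- rest[i, ]
        row[home_col[i]] <- share[i]
        prof[idx_s[i], ] <- row
      }
      home[idx_s] <- conditions[home_col]
    }

    idx_n <- which(classes == "NUNS")
    for (i in idx_n) {
      # keep m expressed conditions (>= 3, <= n-1 so at least one is zero)
      m_lo <- if (mode == "tissue") 3L else max(3L, ceiling(n_cond / 2))
      m <- sample(seq(m_lo, n_cond - 1L), 1L)
      keep <- sample.int(n_cond, m)
      p <- as.numeric(dirichlet_rows(1L, m, alpha = if (mode == "tissue") 3 else 5))
      p <- flatten_below(0.5 * p + 0.5 / m, 0.9 * cutoff)
      prof[i, keep] <- p
    }

    max_abund <- 10^runif(config$n_genes, 0, config$dynamic_range_decades)
    abund <- prof / apply(prof, 1, max) * max_abund

    expression <- as_tibble(abund, .name_repair = ~conditions)
    expression <- dplyr::bind_cols(tibble(gene = genes), expression)
    truth <- tibble(gene = genes, class = classes, condition = home)
    list(expression = expression, truth = truth)
  })
}

#' Simulate a raw replicate table with present/absent calls
#'
#' Emulates array-style raw data: per gene and condition, `replicate_count`
#' noisy signal measurements each carrying a present/absent detection call.
#' Calls are independent Bernoulli draws with per-replicate absence
#' probability `dropout_rate`; signals are the true abundance under
#' multiplicative log-normal noise.
#'
#' @inheritParams simulate_expression_matrix
#' @param noise_sdlog Log-scale standard deviation of replicate noise.
#' @return A list with `replicates` (long tibble: `gene`, `condition`,
#'   `replicate`, `signal`, `call` with values `"present"`/`"absent"`),
#'   plus the underlying `expression` matrix and planted `truth`.
#' @seealso [preprocess_replicates()] for the all-present filter and
#'   replicate averaging.
#' @export
simulate_replicate_table <- function(config,
                                     mode = c("tissue", "stage"),
                                     noise_sdlog = 0.2) {
  mode <- match.arg(mode)
  sim <- simulate_expression_matrix(config, mode)
  long <- tidyr::pivot_longer(
    sim$expression,
    cols = -"gene", names_to = "condition", values_to = "abundance"
  )
  with_seed(child_seed(config$seed, 101), {
    reps <- tidyr::expand_grid(long, replicate = seq_len(config$replicate_count))
    reps$signal <- reps$abundance * rlnorm(nrow(reps), 0, noise_sdlog)
    reps$call <- ifelse(
      runif(nrow(reps)) < config$dropout_rate, "absent", "present"
    )
    replicates <- select(
      reps, "gene", "condition", "replicate", "signal", "call"
    )
    list(replicates = replicates, expression = sim$expression, truth = sim$truth)
  })
}
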