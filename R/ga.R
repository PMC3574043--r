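# GA/SVM wrapper feature selection. A chromosome is a boolean inclusion
# mask over the candidate gene pool; its fitness combines the internally
# cross-validated accuracy of a Gaussian-kernel SVM trained on the selected
# genes with a parsimony bonus for small sets:
#
#   fitness = (1 - weight) * accuracy +
#             weight * (numberOfAllGenes - numberOfSelectedGenes) / numberOfAllGenes
#
# Each generation spawns 160 offspring by roulette-selected parents and
# uniform crossover plus 20 mutated copies of roulette-selected
# chromosomes; the best 200 of the pooled 380 survive.

#' GA/SVM configuration
#'
#' Defaults follow the published operating point of the wrapper: a
#' population of 200 chromosomes of about 15 genes each, 160 offspring and
#' 20 mutants per generation, a bit-flip rate of 0.15 percent, fitness
#' weight 0.2, six-fold internal cross-validation with a Gaussian-kernel
#' SVM at libsvm defaults (cost 1, kernel coefficient 1 / number of
#' selected genes), evolved for 25 generations.
#'
#' @param n_genes Size of the candidate gene pool (mask length).
#' @param population_size Chromosomes kept per generation.
#' @param generations Number of generations.
#' @param n_offspring Offspring created by crossover per generation.
#' @param n_mutants Mutated copies added per generation.
#' @param bit_flip_rate Per-bit mutation probability.
#' @param init_inclusion_prob Per-gene inclusion probability at
#'   initialisation (mean initial set size = `n_genes *
#'   init_inclusion_prob`, 15 by default).
#' @param init_exact_size If non-`NULL`, draw exactly this many genes per
#'   initial chromosome instead of per-gene Bernoulli sampling.
#' @param weight Parsimony weight in the fitness function, in `[0, 1]`.
#' @param internal_cv_folds Folds of the internal accuracy estimate.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(n_genes, population_size = 200, generations = 25,
                      n_offspring = 160, n_mutants = 20,
                      bit_flip_rate = 0.0015,
                      init_inclusion_prob = 15 / n_genes,
                      init_exact_size = NULL, weight = 0.2,
                      internal_cv_folds = 6) {
  stopifnot(n_genes >= 2, population_size >= 2, generations >= 1)
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  if (bit_flip_rate < 0 || bit_flip_rate > 1) {
    stop("bit_flip_rate must lie in [0, 1]")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    n_offspring = as.integer(n_offspring),
    n_mutants = as.integer(n_mutants),
    bit_flip_rate = bit_flip_rate,
    init_inclusion_prob = init_inclusion_prob,
    init_exact_size = init_exact_size,
    weight = weight,
    internal_cv_folds = as.integer(internal_cv_folds)
  ), class = "ga_config")
}

# fitness on the internal (samples x genes) orientation with a frozen fold
# assignment; empty masks score 0 so evolution can proceed past them
fitness_impl <- function(mask, x, y, fold, weight, n_genes) {
  n_sel <- sum(mask)
  if (n_sel == 0L) {
    return(c(fitness = 0, accuracy = NA_real_, parsimony = NA_real_))
  }
  acc <- svm_cv_accuracy(x[, mask, drop = FALSE], y, fold)
  pars <- (n_genes - n_sel) / n_genes
  c(
    fitness = (1 - weight) * acc + weight * pars,
    accuracy = acc, parsimony = pars
  )
}

#' Fitness of one chromosome
#'
#' Scores an inclusion mask by the mean accuracy of a Gaussian-kernel SVM
#' over a stratified internal cross-validation, combined with the parsimony
#' term. An empty mask is assigned fitness 0 (with a message) rather than
#' an error.
#'
#' @param chromosome Logical inclusion mask over the rows of `expr`.
#' @param expr Candidate-pool expression matrix, genes x samples.
#' @param labels Two-level class factor for the samples.
#' @param config A [ga_config()].
#' @param cv_fold Optional integer fold assignment (length = samples);
#'   drawn from the current RNG state when `NULL`.
#' @return Named numeric vector: `fitness`, `accuracy`, `parsimony`.
#' @export
ga_fitness <- function(chromosome, expr, labels, config = ga_config(nrow(expr)),
                       cv_fold = NULL) {
  labels <- check_expr_labels(expr, labels)
  stopifnot(length(chromosome) == nrow(expr))
  if (sum(chromosome) == 0L) {
    message("empty chromosome: fitness set to 0")
    return(c(fitness = 0, accuracy = NA_real_, parsimony = NA_real_))
  }
  if (is.null(cv_fold)) {
    cv_fold <- stratified_fold_ids(labels, config$internal_cv_folds)
  }
  fitness_impl(
    as.logical(chromosome), t(expr), labels, cv_fold,
    config$weight, config$n_genes
  )
}

#' Initial GA population
#'
#' Each gene enters each chromosome independently with probability
#' `init_inclusion_prob` (or exactly `init_exact_size` genes are drawn when
#' set); chromosomes that come out empty are redrawn.
#'
#' @param config A [ga_config()].
#' @return Logical matrix, `population_size` x `n_genes`.
#' @export
ga_init_population <- function(config) {
  stopifnot(inherits(config, "ga_config"))
  pop <- matrix(FALSE, config$population_size, config$n_genes)
  for (i in seq_len(config$population_size)) {
    repeat {
      if (is.null(config$init_exact_size)) {
        mask <- runif(config$n_genes) < config$init_inclusion_prob
      } else {
        mask <- rep(FALSE, config$n_genes)
        mask[sample.int(config$n_genes, config$init_exact_size)] <- TRUE
      }
      if (any(mask)) break
    }
    pop[i, ] <- mask
  }
  pop
}

#' Roulette-wheel selection
#'
#' Returns the index of one chromosome drawn with probability proportional
#' to its fitness; an all-zero fitness vector falls back to a uniform draw.
#'
#' @param fitnesses Non-negative fitness values.
#' @return A single index.
#' @export
ga_roulette_select <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative")
  total <- sum(fitnesses)
  if (total == 0) {
    return(sample.int(length(fitnesses), 1L))
  }
  findInterval(runif(1) * total, cumsum(fitnesses)) + 1L
}

#' Uniform crossover
#'
#' Each position of the child is copied from either parent with equal
#' probability, independently.
#'
#' @param parent_a,parent_b Logical masks of equal length.
#' @return Logical mask.
#' @export
ga_uniform_crossover <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b)) {
    stop("parent masks must have equal length")
  }
  take_a <- runif(length(parent_a)) < 0.5
  ifelse(take_a, parent_a, parent_b)
}

#' Bit-flip mutation
#'
#' Flips each bit independently with probability `rate`.
#'
#' @param chromosome Logical mask.
#' @param rate Per-bit flip probability.
#' @return Logical mask.
#' @export
ga_mutate <- function(chromosome, rate = 0.0015) {
  flip <- runif(length(chromosome)) < rate
  xor(chromosome, flip)
}

#' Fit the GA/SVM wrapper selector
#'
#' Evolves boolean gene-inclusion masks for `generations` rounds: per
#' round, `n_offspring` children from roulette-selected parent pairs and
#' uniform crossover plus `n_mutants` mutated copies of roulette-selected
#' chromosomes join the parents, and the best `population_size` of the
#' pooled candidates survive (elitist truncation, so the best fitness never
#' decreases). The internal CV split is drawn once per fit and frozen, so
#' the fitness cache stays valid. Returns the highest-fitness chromosome's
#' gene set.
#'
#' @param expr Candidate-pool expression matrix, genes x samples (typically
#'   the output of [rank_by_fold_change()]).
#' @param labels Two-level class factor (or annotation data frame).
#' @param config A [ga_config()]; defaults to the published operating
#'   point for `nrow(expr)` genes.
#' @param seed Optional integer seed for this fit.
#' @return An object of class `ga_svm`: list with `genes` (selected
#'   symbols), `mask`, `fitness`, `accuracy`, `trace` (per-generation best
#'   and mean fitness and best set size), `config`, `seed` and `n_evals`
#'   (distinct masks evaluated).
#' @seealso [ga_svm_runs()] for the repeated-run frequency ranking.
#' @export
ga_svm <- function(expr, labels, config = ga_config(nrow(expr)),
                   seed = NULL) {
  if (is.data.frame(labels)) labels <- labels_for(expr, labels)
  labels <- check_expr_labels(expr, labels)
  stopifnot(inherits(config, "ga_config"))
  if (config$n_genes != nrow(expr)) {
    stop("config$n_genes must equal nrow(expr)")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  x <- t(expr)
  fold <- stratified_fold_ids(labels, config$internal_cv_folds)

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  n_evals <- 0L
  eval_mask <- function(mask) {
    key <- paste(which(mask), collapse = ".")
    if (key == "") key <- "empty"
    val <- cache[[key]]
    if (is.null(val)) {
      val <- fitness_impl(mask, x, labels, fold, config$weight, config$n_genes)
      cache[[key]] <- val
      n_evals <<- n_evals + 1L
    }
    val
  }

  pop <- ga_init_population(config)
  fit <- apply(pop, 1, function(m) eval_mask(m)["fitness"])
  trace <- data.frame(
    generation = 0L, best = max(fit), mean = mean(fit),
    best_size = sum(pop[which.max(fit), ])
  )

  for (g in seq_len(config$generations)) {
    extra <- matrix(FALSE, config$n_offspring + config$n_mutants,
      config$n_genes
    )
    for (j in seq_len(config$n_offspring)) {
      p1 <- ga_roulette_select(fit)
      p2 <- ga_roulette_select(fit)
      extra[j, ] <- ga_uniform_crossover(pop[p1, ], pop[p2, ])
    }
    for (j in seq_len(config$n_mutants)) {
      p <- ga_roulette_select(fit)
      extra[config$n_offspring + j, ] <-
        ga_mutate(pop[p, ], config$bit_flip_rate)
    }
    pool <- rbind(pop, extra)
    pool_fit <- c(fit, apply(extra, 1, function(m) eval_mask(m)["fitness"]))
    keep <- order(pool_fit, decreasing = TRUE)[seq_len(config$population_size)]
    pop <- pool[keep, , drop = FALSE]
    fit <- pool_fit[keep]
    trace <- rbind(trace, data.frame(
      generation = g, best = fit[1], mean = mean(fit),
      best_size = sum(pop[1, ])
    ))
  }

  best <- pop[1, ]
  val <- eval_mask(best)
  structure(list(
    genes = rownames(expr)[best], mask = best,
    fitness = unname(val["fitness"]), accuracy = unname(val["accuracy"]),
    trace = trace, config = config, seed = seed, n_evals = n_evals
  ), class = "ga_svm")
}

#' @export
print.ga_svm <- function(x, ...) {
  cat("GA/SVM wrapper selection\n")
  cat(
    "  final set:", length(x$genes), "genes | fitness",
    sprintf("%.4f", x$fitness), "| internal CV accuracy",
    sprintf("%.4f", x$accuracy), "\n"
  )
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ga_svm <- function(object, ...) {
  cat("GA/SVM wrapper selection\n")
  cat(
    "  pool size:", object$config$n_genes, "genes;",
    object$config$generations, "generations; population",
    object$config$population_size, "\n"
  )
  cat(
    "  evaluated", object$n_evals, "distinct masks;",
    "final fitness", sprintf("%.4f", object$fitness),
    "(accuracy", sprintf("%.4f", object$accuracy), ")\n"
  )
  cat("  fitness trace (best):",
    sprintf("%.3f", object$trace$best[1]), "->",
    sprintf("%.3f", object$trace$best[nrow(object$trace)]), "\n"
  )
  cat("  selected genes:", paste(object$genes, collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.ga_svm <- function(x, ...) {
  plot(x$trace$generation, x$trace$best,
    type = "l", lwd = 2,
    xlab = "generation", ylab = "fitness",
    ylim = range(c(x$trace$best, x$trace$mean)),
    main = "GA/SVM fitness trace", ...
  )
  lines(x$trace$generation, x$trace$mean, lty = 2)
  legend("bottomright",
    legend = c("best", "population mean"),
    lty = c(1, 2), lwd = c(2, 1), bty = "n"
  )
  invisible(x)
}

#' Repeated GA/SVM runs and frequency ranking
#'
#' Runs the wrapper `n_runs` times with independently derived seeds and
#' ranks genes by how often they appear in the final sets. The frequency
#' ranking is the wrapper's importance score, comparable to the
#' single-gene rankers.
#'
#' @param expr Candidate-pool expression matrix, genes x samples.
#' @param labels Two-level class factor (or annotation data frame).
#' @param config A [ga_config()].
#' @param n_runs Number of independent runs.
#' @param base_seed Seed from which the per-run seeds are drawn.
#' @return An object of class `ga_svm_runs`: list with `sets` (final gene
#'   sets), `frequency` (ranked data frame `gene`, `score`, `rank`),
#'   `fitnesses`, `traces` (per-run fitness traces), `seeds` and `config`.
#' @export
ga_svm_runs <- function(expr, labels, config = ga_config(nrow(expr)),
                        n_runs = 200, base_seed = 1L) {
  stopifnot(n_runs >= 1)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(2147483646L, n_runs)
  sets <- vector("list", n_runs)
  fitnesses <- numeric(n_runs)
  traces <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run <- ga_svm(expr, labels, config, seed = seeds[r])
    sets[[r]] <- run$genes
    fitnesses[r] <- run$fitness
    traces[[r]] <- run$trace
  }
  structure(list(
    sets = sets, frequency = frequency_rank(sets),
    fitnesses = fitnesses, traces = traces, seeds = seeds, config = config,
    base_seed = as.integer(base_seed)
  ), class = "ga_svm_runs")
}

#' @export
print.ga_svm_runs <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat("GA/SVM repeated runs:", length(x$sets), "final sets\n")
  cat(
    "  set sizes: median", median(sizes), "(range", min(sizes), "-",
    max(sizes), ")\n"
  )
  cat(
    "  top genes:",
    paste(utils::head(x$frequency$gene, 10), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @export
summary.ga_svm_runs <- function(object, ...) {
  print(object)
  cat(
    "  mean final fitness:", sprintf("%.4f", mean(object$fitnesses)),
    "\n"
  )
  invisible(object)
}
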