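# Synthetic two-class expression data with planted markers, redundancy
# blocks and subject-level correlation. The generator mirrors the structure
# of a multi-region brain expression study: each subject contributes one
# sample per region (stratum), the disease state is a property of the
# subject, and only a minority of genes carry class signal.

#' Configuration for the synthetic expression generator
#'
#' Defines a two-class log-scale expression study. Class labels are assigned
#' at the subject level (a brain is affected or healthy as a whole), every
#' subject contributes `samples_per_subject` samples (one per stratum), and
#' each gene value is the sum of: a class shift for informative genes, a
#' shared latent signal for redundancy-block members, a subject-level random
#' intercept, and independent Gaussian noise.
#'
#' @param n_genes Number of genes.
#' @param n_subjects Number of subjects; each yields `samples_per_subject`
#'   samples.
#' @param samples_per_subject Samples per subject; also the number of strata
#'   (each subject has exactly one sample per stratum).
#' @param n_informative Number of independent informative genes. Their class
#'   shift alternates in sign so the panel contains both up- and
#'   down-regulated markers.
#' @param effect_size Class-mean shift of informative genes, in units of
#'   `noise_sd`.
#' @param n_redundancy_blocks,block_size Number and size of mutually
#'   redundant gene blocks; members of a block share a latent Gaussian
#'   signal.
#' @param block_correlation Target pairwise Pearson correlation between
#'   members of a block (from the latent-mixing weight; subject effects add
#'   a little on top).
#' @param block_effect_size Optional class shift (in `noise_sd` units)
#'   carried by every member of a block, making the block redundant *and*
#'   informative. Default 0 (blocks are pure correlated noise).
#' @param subject_effect_sd SD of the per-(subject, gene) random intercept
#'   shared by all samples of one subject.
#' @param noise_sd SD of the independent residual noise.
#' @param class_balance Fraction of subjects in the affected class.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 1000, n_subjects = 40,
                         samples_per_subject = 4, n_informative = 20,
                         effect_size = 1.5, n_redundancy_blocks = 4,
                         block_size = 5, block_correlation = 0.8,
                         block_effect_size = 0, subject_effect_sd = 0.5,
                         noise_sd = 1, class_balance = 0.5, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_subjects = as.integer(n_subjects),
    samples_per_subject = as.integer(samples_per_subject),
    n_informative = as.integer(n_informative), effect_size = effect_size,
    n_redundancy_blocks = as.integer(n_redundancy_blocks),
    block_size = as.integer(block_size),
    block_correlation = block_correlation,
    block_effect_size = block_effect_size,
    subject_effect_sd = subject_effect_sd, noise_sd = noise_sd,
    class_balance = class_balance, seed = as.integer(seed)
  )
  if (cfg$n_informative + cfg$n_redundancy_blocks * cfg$block_size >
    cfg$n_genes) {
    stop("n_informative + n_redundancy_blocks * block_size must not exceed n_genes")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$subject_effect_sd < 0) stop("subject_effect_sd must be >= 0")
  if (cfg$block_correlation < 0 || cfg$block_correlation >= 1) {
    stop("block_correlation must be in [0, 1)")
  }
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1) {
    stop("class_balance must be strictly between 0 and 1")
  }
  n_aff <- round(cfg$n_subjects * cfg$class_balance)
  if (n_aff < 1 || n_aff >= cfg$n_subjects) {
    stop("class_balance leaves one class empty")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic two-class expression dataset
#'
#' Draws an expression matrix, its sample annotation and the generating
#' ground truth from a [synth_config()]. Affected samples of an informative
#' gene are shifted by `effect_size * noise_sd` (alternating sign across
#' genes); members of a redundancy block equal a scaled per-sample latent
#' Gaussian plus independent noise, with the mixing weight solved so the
#' within-block correlation matches `block_correlation`; all samples of a
#' subject share a per-gene random intercept.
#'
#' @param config A [synth_config()].
#' @return An object of class `synth_dataset`: a list with `expr` (numeric
#'   matrix, genes x samples), `annotation` (data frame with `sample_id`,
#'   `class_label`, `subject_id`, `stratum`), `truth` (list with
#'   `informative_genes`, `redundancy_blocks`, `effect_sizes`) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  c_ <- config
  set.seed(c_$seed)

  n_samples <- c_$n_subjects * c_$samples_per_subject
  subjects <- sprintf("S%03d", seq_len(c_$n_subjects))
  n_aff <- round(c_$n_subjects * c_$class_balance)
  subj_class <- rep(c("affected", "control"),
    c(n_aff, c_$n_subjects - n_aff)
  )
  annotation <- data.frame(
    sample_id = sprintf(
      "%s_r%d", rep(subjects, each = c_$samples_per_subject),
      rep(seq_len(c_$samples_per_subject), c_$n_subjects)
    ),
    class_label = rep(subj_class, each = c_$samples_per_subject),
    subject_id = rep(subjects, each = c_$samples_per_subject),
    stratum = sprintf("region%d", rep(
      seq_len(c_$samples_per_subject),
      c_$n_subjects
    )),
    stringsAsFactors = FALSE
  )
  genes <- sprintf("g%04d", seq_len(c_$n_genes))
  affected <- annotation$class_label == "affected"

  # residual noise
  expr <- matrix(rnorm(c_$n_genes * n_samples, sd = c_$noise_sd),
    nrow = c_$n_genes, dimnames = list(genes, annotation$sample_id)
  )

  # per-(subject, gene) random intercept shared by the subject's samples
  if (c_$subject_effect_sd > 0) {
    u <- matrix(rnorm(c_$n_genes * c_$n_subjects, sd = c_$subject_effect_sd),
      nrow = c_$n_genes
    )
    expr <- expr + u[, match(annotation$subject_id, subjects)]
  }

  effect_sizes <- setNames(numeric(c_$n_genes), genes)
  informative <- character(0)
  if (c_$n_informative > 0) {
    informative <- genes[seq_len(c_$n_informative)]
    signs <- rep_len(c(1, -1), c_$n_informative)
    shift <- signs * c_$effect_size * c_$noise_sd
    expr[informative, affected] <- expr[informative, affected] + shift
    effect_sizes[informative] <- shift
  }

  blocks <- list()
  if (c_$n_redundancy_blocks > 0 && c_$block_size > 0) {
    rho <- c_$block_correlation
    lambda <- c_$noise_sd * sqrt(rho / (1 - rho))
    offset <- c_$n_informative
    for (b in seq_len(c_$n_redundancy_blocks)) {
      members <- genes[offset + (b - 1L) * c_$block_size +
        seq_len(c_$block_size)]
      latent <- rnorm(n_samples)
      expr[members, ] <- expr[members, ] +
        matrix(lambda * latent, c_$block_size, n_samples, byrow = TRUE)
      if (c_$block_effect_size != 0) {
        shift <- c_$block_effect_size * c_$noise_sd
        expr[members, affected] <- expr[members, affected] + shift
        effect_sizes[members] <- shift
      }
      blocks[[b]] <- members
    }
  }

  structure(list(
    expr = expr, annotation = annotation,
    truth = list(
      informative_genes = informative, redundancy_blocks = blocks,
      effect_sizes = effect_sizes
    ),
    config = c_
  ), class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(
    "Synthetic expression dataset:", nrow(x$expr), "genes x",
    ncol(x$expr), "samples\n"
  )
  cat(
    " ", length(unique(x$annotation$subject_id)), "subjects,",
    sum(x$annotation$class_label == "affected"), "affected /",
    sum(x$annotation$class_label == "control"), "control samples\n"
  )
  cat(
    " ", length(x$truth$informative_genes), "informative genes,",
    length(x$truth$redundancy_blocks), "redundancy blocks\n"
  )
  invisible(x)
}

#' Build reference gene lists from the generating truth
#'
#' Emits one list enriched in the planted informative genes (a stated
#' fraction of them plus random background fillers) and one or more decoy
#' lists drawn uniformly from the background, for exercising
#' over-representation analysis end to end.
#'
#' @param dataset A `synth_dataset` (or its `truth` plus gene universe).
#' @param fraction Fraction of informative genes included in the enriched
#'   list.
#' @param n_fillers Number of background genes appended to the enriched
#'   list.
#' @param n_decoys Number of decoy lists.
#' @param decoy_size Size of each decoy list.
#' @param seed Integer seed.
#' @return Named list of character vectors (`informative_enriched`,
#'   `decoy_1`, ...).
#' @export
generate_reference_lists <- function(dataset, fraction = 1, n_fillers = 0,
                                     n_decoys = 1, decoy_size = 50,
                                     seed = 1L) {
  stopifnot(inherits(dataset, "synth_dataset"))
  set.seed(as.integer(seed))
  universe <- rownames(dataset$expr)
  informative <- dataset$truth$informative_genes
  background <- setdiff(universe, informative)
  n_inf <- round(fraction * length(informative))
  if (n_inf + n_fillers > length(universe) || decoy_size > length(background)) {
    stop("requested list larger than the available gene universe")
  }
  enriched <- informative[seq_len(n_inf)]
  if (fraction < 1) enriched <- sort(sample(informative, n_inf))
  if (n_fillers > 0) enriched <- c(enriched, sort(sample(background, n_fillers)))
  lists <- list(informative_enriched = enriched)
  for (d in seq_len(n_decoys)) {
    lists[[paste0("decoy_", d)]] <- sort(sample(background, decoy_size))
  }
  lists
}
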