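#' Simulation configuration for two-condition expression data
#'
#' Builds and validates the parameter set for [generate_dataset()]. The
#' defaults emulate a small two-condition microarray study: two diet groups
#' with 3 and 4 arrays, a few thousand genes on the log2 scale, a planted
#' set of differential genes at a 4-fold effect, and tightly co-regulated
#' gene modules that exercise the |r| > 0.999 co-expression edge rule.
#'
#' @param seed integer seed; together with the other fields it fully
#'   determines the generated data.
#' @param n_genes number of genes (rows).
#' @param n_samples_a,n_samples_b replicates in conditions A and B
#'   (defaults 3 and 4, the unequal small-n design this pipeline targets).
#' @param baseline_mean,baseline_sd per-gene baseline log2 intensity is drawn
#'   from N(baseline_mean, baseline_sd^2).
#' @param de_fraction proportion of genes planted as differential, in [0, 1].
#' @param de_log2fc absolute planted log2 fold change (condition B minus A);
#'   sign is randomised per gene.
#' @param noise_sd within-group Gaussian noise SD on the log2 scale for
#'   genes outside correlation modules.
#' @param modules list of module specifications from [module_spec()];
#'   module genes are drawn from the non-differential pool and are disjoint
#'   across modules.
#' @param n_categories number of annotation categories for
#'   [generate_annotation()].
#' @param category_size_range integer pair, inclusive bounds for category
#'   sizes.
#' @param de_enrichment_boost odds multiplier >= 1: boosted categories
#'   over-sample planted differential genes with these odds. At 1, category
#'   membership is independent of differential status.
#' @return a list of class `simulation_config`.
#' @seealso [generate_dataset()], [generate_annotation()]
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000L,
                              n_samples_a = 3L,
                              n_samples_b = 4L,
                              baseline_mean = 8,
                              baseline_sd = 1.5,
                              de_fraction = 0.075,
                              de_log2fc = 2,
                              noise_sd = 0.1,
                              modules = list(),
                              n_categories = 40L,
                              category_size_range = c(10L, 50L),
                              de_enrichment_boost = 1) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != floor(x)) {
      stop("'", field, "' must be a positive integer", call. = FALSE)
    }
    as.integer(x)
  }
  seed <- chk_count(seed, "seed")
  n_genes <- chk_count(n_genes, "n_genes")
  n_samples_a <- chk_count(n_samples_a, "n_samples_a")
  n_samples_b <- chk_count(n_samples_b, "n_samples_b")
  if (!is.numeric(de_fraction) || length(de_fraction) != 1L ||
      is.na(de_fraction) || de_fraction < 0 || de_fraction > 1) {
    stop("'de_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (de_fraction > 0 && de_fraction * n_genes < 1) {
    stop("'de_fraction' times 'n_genes' must be at least 1 when positive",
         call. = FALSE)
  }
  if (!is.numeric(de_log2fc) || de_log2fc <= 0) {
    stop("'de_log2fc' must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(baseline_sd) || baseline_sd < 0) {
    stop("'baseline_sd' must be non-negative", call. = FALSE)
  }
  if (!is.list(modules)) stop("'modules' must be a list", call. = FALSE)
  for (m in modules) {
    if (!inherits(m, "module_spec")) {
      stop("'modules' entries must come from module_spec()", call. = FALSE)
    }
    if (m$size > n_genes) {
      stop("module 'size' exceeds 'n_genes'", call. = FALSE)
    }
  }
  if (!is.numeric(n_categories) || length(n_categories) != 1L ||
      n_categories < 0 || n_categories != floor(n_categories)) {
    stop("'n_categories' must be a non-negative integer", call. = FALSE)
  }
  if (length(category_size_range) != 2L ||
      any(category_size_range < 1) ||
      category_size_range[1] > category_size_range[2]) {
    stop("'category_size_range' must be an increasing pair of positive integers",
         call. = FALSE)
  }
  if (!is.numeric(de_enrichment_boost) || de_enrichment_boost < 1) {
    stop("'de_enrichment_boost' must be >= 1", call. = FALSE)
  }
  structure(list(
    seed = seed, n_genes = n_genes,
    n_samples_a = n_samples_a, n_samples_b = n_samples_b,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    noise_sd = noise_sd, modules = modules,
    n_categories = as.integer(n_categories),
    category_size_range = as.integer(category_size_range),
    de_enrichment_boost = de_enrichment_boost
  ), class = "simulation_config")
}

#' Specify a planted co-expression module
#'
#' A module is a set of genes sharing one latent factor per sample, so that
#' as `residual_sd` approaches 0 all within-module pairwise Pearson
#' correlations approach +/-1 (the per-gene loading sign is randomised).
#' `condition_specific` modules draw independent noise in the inactive
#' condition, which plants a degree-difference signal for the
#' core-regulator ranking.
#'
#' @param size number of genes in the module (>= 3).
#' @param latent_sd SD of the shared latent factor (log2 units).
#' @param residual_sd SD of per-gene residual noise around the latent
#'   factor; 0 makes every member an exact affine image of the factor.
#' @param condition_specific one of `"both"`, `"A_only"`, `"B_only"`.
#' @param de if `TRUE` the module is planted among the differential genes
#'   (so it survives DEG selection and reaches the network stage, mirroring
#'   co-expressed clusters inside a differential gene list); keep
#'   `latent_sd` well below the planted effect size in that case so the
#'   module does not drown its own differential signal.
#' @return a list of class `module_spec`.
#' @export
module_spec <- function(size, latent_sd = 1, residual_sd = 0,
                        condition_specific = c("both", "A_only", "B_only"),
                        de = FALSE) {
  condition_specific <- match.arg(condition_specific)
  if (!is.numeric(size) || size < 3 || size != floor(size)) {
    stop("module 'size' must be an integer >= 3", call. = FALSE)
  }
  if (!is.numeric(latent_sd) || latent_sd <= 0) {
    stop("'latent_sd' must be positive", call. = FALSE)
  }
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    stop("'residual_sd' must be non-negative", call. = FALSE)
  }
  structure(list(size = as.integer(size), latent_sd = latent_sd,
                 residual_sd = residual_sd,
                 condition_specific = condition_specific,
                 de = isTRUE(de)),
            class = "module_spec")
}

pad_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Generate a synthetic two-condition expression dataset
#'
#' Draws a genes-by-samples log2 expression matrix with known truth:
#' planted differential genes (condition B shifted by a signed log2 fold
#' change), planted correlation modules, and Gaussian noise. Identical
#' configuration (including seed) yields identical output.
#'
#' @param config a [simulation_config()].
#' @return a list with components
#'   \describe{
#'     \item{matrix}{numeric matrix, genes x samples, log2 intensities.}
#'     \item{design}{data.frame with columns `sample` and `condition`
#'       (labels `"A"` and `"B"`).}
#'     \item{truth}{list with `de_genes` (data.frame `gene`, `log2fc` of
#'       planted signed effects), `module_membership` (named integer
#'       vector, gene -> module index) and `modules` (list of gene-ID
#'       vectors).}
#'   }
#' @examples
#' cfg <- simulation_config(seed = 1, n_genes = 100, de_fraction = 0.1)
#' sim <- generate_dataset(cfg)
#' dim(sim$matrix)
#' nrow(sim$truth$de_genes)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n_g <- config$n_genes
  n_a <- config$n_samples_a
  n_b <- config$n_samples_b
  genes <- pad_ids("G", n_g)
  samples <- c(pad_ids("A", n_a), pad_ids("B", n_b))
  cond <- rep(c("A", "B"), c(n_a, n_b))

  n_de <- as.integer(floor(config$de_fraction * n_g))
  de_idx <- if (n_de > 0) sort(sample.int(n_g, n_de)) else integer(0)
  de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)

  is_de_mod <- vapply(config$modules, function(m) isTRUE(m$de), logical(1))
  module_sizes <- vapply(config$modules, `[[`, integer(1), "size")
  if (sum(module_sizes[!is_de_mod]) > n_g - n_de) {
    stop("modules do not fit among non-differential genes", call. = FALSE)
  }
  if (sum(module_sizes[is_de_mod]) > n_de) {
    stop("differential modules do not fit among planted differential genes",
         call. = FALSE)
  }
  pool_free <- setdiff(seq_len(n_g), de_idx)
  pool_de <- de_idx
  module_idx <- vector("list", length(config$modules))
  for (j in seq_along(config$modules)) {
    pool <- if (is_de_mod[j]) pool_de else pool_free
    picked <- sort(pool[sample.int(length(pool), config$modules[[j]]$size)])
    module_idx[[j]] <- picked
    if (is_de_mod[j]) pool_de <- setdiff(pool_de, picked)
    else pool_free <- setdiff(pool_free, picked)
  }

  baseline <- stats::rnorm(n_g, config$baseline_mean, config$baseline_sd)
  mu <- matrix(baseline, n_g, n_a + n_b)
  if (n_de > 0) {
    mu[de_idx, cond == "B"] <- mu[de_idx, cond == "B"] +
      de_sign * config$de_log2fc
  }

  x <- mu + matrix(stats::rnorm(n_g * (n_a + n_b), 0, config$noise_sd),
                   n_g, n_a + n_b)

  # module genes: replace global noise with latent-factor structure
  for (j in seq_along(config$modules)) {
    m <- config$modules[[j]]
    idx <- module_idx[[j]]
    loading <- sample(c(-1, 1), m$size, replace = TRUE)
    for (cc in c("A", "B")) {
      cols <- which(cond == cc)
      active <- switch(m$condition_specific,
                       both = TRUE,
                       A_only = cc == "A",
                       B_only = cc == "B")
      if (active) {
        latent <- stats::rnorm(length(cols), 0, m$latent_sd)
        x[idx, cols] <- mu[idx, cols] + outer(loading, latent) +
          matrix(stats::rnorm(m$size * length(cols), 0, m$residual_sd),
                 m$size, length(cols))
      } else {
        x[idx, cols] <- mu[idx, cols] +
          matrix(stats::rnorm(m$size * length(cols), 0,
                              sqrt(m$latent_sd^2 + m$residual_sd^2)),
                 m$size, length(cols))
      }
    }
  }

  dimnames(x) <- list(genes, samples)
  membership <- integer(0)
  for (j in seq_along(module_idx)) {
    mm <- rep.int(j, length(module_idx[[j]]))
    names(mm) <- genes[module_idx[[j]]]
    membership <- c(membership, mm)
  }
  list(
    matrix = x,
    design = data.frame(sample = samples, condition = cond,
                        stringsAsFactors = FALSE),
    truth = list(
      de_genes = data.frame(gene = genes[de_idx],
                            log2fc = de_sign * config$de_log2fc,
                            stringsAsFactors = FALSE),
      module_membership = membership,
      modules = lapply(module_idx, function(i) genes[i])
    )
  )
}

#' Generate gene-to-category annotations with optional planted enrichment
#'
#' Draws `n_categories` categories of sizes uniform in
#' `category_size_range`. A fixed leading fraction of categories (one in
#' five, at least one when a boost is requested) is flagged "boosted":
#' those categories sample planted differential genes with odds multiplied
#' by `de_enrichment_boost`. At boost = 1 membership is independent of
#' differential status; at boost = Inf boosted categories contain only
#' differential genes (as far as their size allows).
#'
#' @param truth the `truth` component of [generate_dataset()] output.
#' @param config the same [simulation_config()] used for the dataset.
#' @param genes character vector of all gene IDs (the matrix rownames).
#' @return a list with `annotation` (data.frame `gene`, `category`) and
#'   `boosted` (character vector of boosted category IDs).
#' @export
generate_annotation <- function(truth, config, genes) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n_cat <- config$n_categories
  if (n_cat == 0L) {
    return(list(annotation = data.frame(gene = character(0),
                                        category = character(0),
                                        stringsAsFactors = FALSE),
                boosted = character(0)))
  }
  cats <- pad_ids("C", n_cat)
  boost <- config$de_enrichment_boost
  n_boost <- if (boost > 1) max(1L, n_cat %/% 5L) else 0L
  boosted <- cats[seq_len(n_boost)]
  de <- truth$de_genes$gene
  is_de <- genes %in% de
  lo <- config$category_size_range[1]
  hi <- config$category_size_range[2]
  out <- vector("list", n_cat)
  for (j in seq_len(n_cat)) {
    size <- if (lo == hi) lo else sample(lo:hi, 1L)
    size <- min(size, length(genes))
    if (cats[j] %in% boosted) {
      if (is.infinite(boost)) {
        members <- if (size <= length(de)) {
          sample(de, size)
        } else {
          c(de, sample(genes[!is_de], size - length(de)))
        }
      } else {
        w <- ifelse(is_de, boost, 1)
        members <- sample(genes, size, prob = w)
      }
    } else {
      members <- sample(genes, size)
    }
    out[[j]] <- data.frame(gene = members, category = cats[j],
                           stringsAsFactors = FALSE)
  }
  list(annotation = do.call(rbind, out), boosted = boosted)
}
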