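#' Genetic-algorithm configuration for wrapper feature selection
#'
#' A steady-state GA over binary chromosomes of the feature-set width: bit
#' `i` set means feature `i` is retained. Fitness is the stratified
#' cross-validated accuracy of the wrapped classifier on the selected
#' subset. Parent selection is roulette-wheel (probability proportional to
#' fitness; uniform when all fitnesses are zero), recombination is standard
#' two-point crossover at `crossover_rate`, and mutation flips each bit
#' independently at `mutation_rate`. The offspring replaces the current
#' worst individual only when fitter, so the best fitness is monotone. One
#' "generation" is `population_size` offspring events.
#'
#' @param population_size Number of chromosomes maintained.
#' @param max_generations Stopping point, in generations.
#' @param crossover_rate Probability that crossover (rather than cloning
#'   the first parent) produces the offspring.
#' @param mutation_rate Per-bit flip probability.
#' @param cv_folds Stratified folds used by the fitness evaluation.
#' @param fitness_classifier Classifier kind scoring subsets (default LDA).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, max_generations = 30L,
                      crossover_rate = 0.8, mutation_rate = 0.01,
                      cv_folds = 5L, fitness_classifier = "lda",
                      seed = 1L) {
  stopifnot(population_size >= 2, max_generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, cv_folds >= 2)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 cv_folds = as.integer(cv_folds),
                 fitness_classifier = fitness_classifier,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Decode a binary chromosome into feature indices
#'
#' Bit `i` set to 1 selects feature `i`; e.g. `"10100010"` selects features
#' 1, 3 and 7.
#'
#' @param bits A string of 0/1 characters or a 0/1 integer vector.
#' @return Sorted integer vector of selected (1-based) indices.
#' @examples
#' decode_chromosome("10100010")
#' @export
decode_chromosome <- function(bits) {
  bits <- as_bits(bits)
  which(bits == 1L)
}

as_bits <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1)
    ch <- strsplit(bits, "")[[1]]
    if (!all(ch %in% c("0", "1"))) {
      abort(sprintf("chromosome contains non-binary characters: '%s'",
                    paste(setdiff(unique(ch), c("0", "1")), collapse = "")))
    }
    return(as.integer(ch))
  }
  bits <- as.integer(bits)
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L))) {
    abort("chromosome bits must be 0 or 1")
  }
  bits
}

#' Encode an index set as a chromosome bit vector
#'
#' Inverse of [decode_chromosome()].
#'
#' @param indices 1-based feature indices.
#' @param d Chromosome length.
#' @return Integer 0/1 vector of length `d`.
#' @export
encode_chromosome <- function(indices, d) {
  stopifnot(all(indices >= 1), all(indices <= d))
  bits <- integer(d)
  bits[indices] <- 1L
  bits
}

#' Chromosome fitness: cross-validated subset accuracy
#'
#' Mean stratified `cv_folds`-fold accuracy of the configured classifier
#' trained on the features the chromosome selects. The all-zero chromosome
#' has fitness 0 by convention. Results are memoised by bit pattern when a
#' cache environment is supplied, so re-evaluating a pattern costs nothing.
#'
#' @param bits Chromosome (string or 0/1 vector).
#' @param x Feature matrix/tibble (already normalised).
#' @param y Labels, one per row.
#' @param cfg A [ga_config()].
#' @param cache Optional environment used as a memo table; its `evals`
#'   field counts actual cross-validation runs.
#' @return Accuracy in `[0, 1]`.
#' @export
chromosome_fitness <- function(bits, x, y, cfg = ga_config(), cache = NULL) {
  bits <- as_bits(bits)
  key <- paste(bits, collapse = "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sel <- which(bits == 1L)
  val <- if (!length(sel)) 0 else {
    x <- feature_block(x)
    cv_accuracy(x[, sel, drop = FALSE], y,
                kind = cfg$fitness_classifier, k = cfg$cv_folds)
  }
  if (!is.null(cache)) {
    cache[[key]] <- val
    cache$evals <- (cache$evals %||% 0L) + (if (length(sel)) 1L else 0L)
  }
  val
}

# Stratified k-fold CV accuracy of one classifier kind. Fold assignment
# consumes the current RNG stream (callers seed it).
cv_accuracy <- function(x, y, kind = "lda", k = 5L) {
  folds <- stratified_folds(y, k)
  mean(vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- train_classifier(x[tr, , drop = FALSE], y[tr], kind)
    mean(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1)))
}

#' Two-point crossover
#'
#' With probability `rate` the offspring is the first parent with the
#' segment between two random cut points replaced by the second parent's
#' segment; otherwise it is a copy of the first parent. No novel alleles
#' are introduced.
#'
#' @param p1,p2 Parent chromosomes (equal-length 0/1 vectors).
#' @param rate Crossover probability.
#' @param cuts Optional fixed cut points `c(c1, c2)` with
#'   `0 <= c1 < c2 <= d` (mainly for tests); random when `NULL`.
#' @return Offspring 0/1 vector.
#' @export
two_point_crossover <- function(p1, p2, rate = 0.8, cuts = NULL) {
  p1 <- as_bits(p1); p2 <- as_bits(p2)
  if (length(p1) != length(p2)) abort("parent chromosomes differ in length")
  d <- length(p1)
  if (runif(1) > rate && is.null(cuts)) return(p1)
  if (is.null(cuts)) cuts <- sort(sample(0:d, 2, replace = FALSE))
  stopifnot(length(cuts) == 2, cuts[1] >= 0, cuts[2] <= d, cuts[1] <= cuts[2])
  off <- p1
  if (cuts[2] > cuts[1]) {
    seg <- (cuts[1] + 1):cuts[2]
    off[seg] <- p2[seg]
  }
  off
}

#' Bit-flip mutation
#'
#' Each bit flips independently with probability `rate` (the binary-GA
#' realisation of per-gene mutation at the configured probability);
#' expected Hamming distance is `length(bits) * rate`.
#'
#' @param bits Chromosome.
#' @param rate Per-bit flip probability.
#' @return Mutated 0/1 vector.
#' @export
mutate_chromosome <- function(bits, rate = 0.01) {
  bits <- as_bits(bits)
  flip <- runif(length(bits)) < rate
  bits[flip] <- 1L - bits[flip]
  bits
}

#' Roulette-wheel parent selection
#'
#' Samples one population index with probability proportional to fitness;
#' when the total fitness is zero the draw is uniform.
#'
#' @param fitness Numeric vector of non-negative fitnesses.
#' @return Integer index.
#' @export
roulette_select <- function(fitness) {
  stopifnot(length(fitness) >= 1, all(fitness >= 0))
  if (sum(fitness) <= 0) return(sample.int(length(fitness), 1))
  sample.int(length(fitness), 1, prob = fitness)
}

#' Run the steady-state genetic algorithm
#'
#' Maintains a population of `population_size` chromosomes over the feature
#' columns of `x`. Each breeding event selects two parents by roulette
#' wheel, produces one offspring by two-point crossover and bit-flip
#' mutation, evaluates it, and replaces the current worst individual if the
#' offspring is fitter. `max_generations * population_size` events are
#' performed; the best fitness per generation is recorded and is
#' non-decreasing by construction.
#'
#' @param x Normalised feature matrix or tibble (columns = candidate
#'   features).
#' @param y Labels, one per row.
#' @param cfg A [ga_config()].
#' @return A `ga_result` with `best_chromosome` (0/1 vector),
#'   `best_fitness`, `best_generation` (generation at which the final best
#'   fitness first appeared; 0 = initial population), `history` (best
#'   fitness after initialisation and after each generation), `selected`
#'   (decoded indices), `n_evals` (distinct fitness evaluations) and the
#'   config.
#' @export
run_ga <- function(x, y, cfg = ga_config()) {
  x <- feature_block(x)
  d <- ncol(x)
  cache <- new.env(parent = emptyenv())
  with_seed(cfg$seed, {
    pop <- matrix(rbinom(cfg$population_size * d, 1L, 0.5),
                  nrow = cfg$population_size)
    fit <- vapply(seq_len(cfg$population_size),
                  function(i) chromosome_fitness(pop[i, ], x, y, cfg, cache),
                  numeric(1))
    history <- max(fit)
    best_gen <- 0L
    for (gen in seq_len(cfg$max_generations)) {
      for (ev in seq_len(cfg$population_size)) {
        i1 <- roulette_select(fit)
        i2 <- roulette_select(fit)
        off <- two_point_crossover(pop[i1, ], pop[i2, ], cfg$crossover_rate)
        off <- mutate_chromosome(off, cfg$mutation_rate)
        f_off <- chromosome_fitness(off, x, y, cfg, cache)
        worst <- which.min(fit)
        if (f_off > fit[worst]) {
          pop[worst, ] <- off
          fit[worst] <- f_off
        }
      }
      gen_best <- max(fit)
      if (gen_best > history[length(history)] + 1e-12) best_gen <- gen
      history <- c(history, gen_best)
    }
    ibest <- which.max(fit)
    structure(list(best_chromosome = pop[ibest, ],
                   best_fitness = fit[ibest],
                   best_generation = best_gen,
                   history = history,
                   selected = which(pop[ibest, ] == 1L),
                   n_evals = cache$evals %||% 0L,
                   config = cfg,
                   feature_names = colnames(x)),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result: %d/%d features, fitness %.4f (first reached at generation %d of %d)>\n",
    length(x$selected), length(x$best_chromosome), x$best_fitness,
    x$best_generation, x$config$max_generations))
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history) - 1L,
                 best_fitness = x$history)
}

#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 best_generation = x$best_generation,
                 n_features = length(x$selected),
                 n_evals = x$n_evals)
}

#' Format a chromosome as channel-wise bit strings
#'
#' Splits a 36-bit chromosome into the three 12-bit channel blocks
#' (BVP / ECG / SCL), the layout used when reporting selected subsets.
#'
#' @param bits Chromosome of length 36.
#' @return Named character vector of three 12-character bit strings.
#' @export
format_chromosome <- function(bits) {
  bits <- as_bits(bits)
  stopifnot(length(bits) == 36)
  blocks <- split(bits, rep(1:3, each = 12))
  stats::setNames(vapply(blocks, paste, character(1), collapse = ""),
                  c("bvp", "ecg", "scl"))
}
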