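#' Write a trial tensor to long-format CSV
#'
#' One row per `(neuron, stimulus, decision, time bin, trial)` with the
#' firing rate in spikes/s; padding entries are omitted, so the file also
#' encodes the per-condition trial counts.
#'
#' @param data a [trial_tensor()].
#' @param path output file path.
#' @export
write_trial_tensor <- function(data, path) {
  stopifnot(inherits(data, "trial_tensor"))
  d <- dim(data$values)
  idx <- which(!is.na(data$values), arr.ind = TRUE)
  df <- data.frame(neuron = idx[, 1], s = idx[, 2], d = idx[, 3],
                   t = idx[, 4], k = idx[, 5],
                   rate = data$values[idx])
  df <- df[order(df$neuron, df$s, df$d, df$t, df$k), ]
  utils::write.csv(df, path, row.names = FALSE)
  tm <- data.frame(t = seq_along(data$time), time = data$time)
  utils::write.csv(tm, paste0(path, ".time"), row.names = FALSE)
  invisible(path)
}

#' Read a trial tensor from long-format CSV
#'
#' Inverse of [write_trial_tensor()]. Validates that all neuron, stimulus,
#' decision and time indices form complete ranges and that every
#' `(neuron, stimulus, decision)` combination is present — the
#' marginalization procedure requires all parameter combinations.
#'
#' @param path CSV file with columns `neuron, s, d, t, k, rate`.
#' @return a [trial_tensor()].
#' @export
read_trial_tensor <- function(path) {
  df <- utils::read.csv(path)
  need <- c("neuron", "s", "d", "t", "k", "rate")
  if (!all(need %in% names(df)))
    stop("malformed file: expected columns ", paste(need, collapse = ", "))
  N <- max(df$neuron); S <- max(df$s); Q <- max(df$d)
  T_ <- max(df$t); K <- max(df$k)
  counts <- array(0L, dim = c(N, S, Q))
  vals <- array(NA_real_, dim = c(N, S, Q, T_, K))
  vals[cbind(df$neuron, df$s, df$d, df$t, df$k)] <- df$rate
  cnt <- stats::aggregate(k ~ neuron + s + d, data = df, FUN = max)
  counts[cbind(cnt$neuron, cnt$s, cnt$d)] <- cnt$k
  if (any(counts == 0L)) {
    bad <- which(counts == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("missing condition: neuron %d, stimulus %d, ",
                        "decision %d has no trials; all parameter ",
                        "combinations must be present"),
                 bad[1], bad[2], bad[3]))
  }
  tmf <- paste0(path, ".time")
  tm <- if (file.exists(tmf)) utils::read.csv(tmf)$time else NULL
  trial_tensor(vals, counts, time = tm)
}

# matrices <-> nested lists for JSON round-trips
.mat_to_list <- function(m) list(nrow = nrow(m), ncol = ncol(m),
                                 data = as.numeric(m))
.list_to_mat <- function(l) matrix(l$data, l$nrow, l$ncol)

#' Serialize a fitted dPCA model to JSON
#'
#' Stores decoders, encoders, the component table and fit metadata
#' (`lambda`, shapes, centering means, component ordering) in a single
#' human-readable JSON file. The training PSTH and marginalization set are
#' not stored; [dpca_load()] therefore returns a model usable for
#' [dpca_transform()] on new data.
#'
#' @param model a [dpca_fit()] result.
#' @param path output JSON path.
#' @export
dpca_save <- function(model, path) {
  stopifnot(inherits(model, "dpca"))
  obj <- list(
    labels = names(model$F),
    F = lapply(model$F, .mat_to_list),
    D = lapply(model$D, .mat_to_list),
    comp = model$comp,
    lambda = model$lambda, mu = model$mu,
    noise_weight = model$noise_weight,
    means = model$means, dims = model$dims, time = model$time,
    Xnorm2 = model$Xnorm2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a dPCA model saved by [dpca_save()]
#'
#' @param path JSON file path.
#' @return an object of class `dpca` (without the stored training PSTH).
#' @export
dpca_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Fs <- lapply(obj$F, .list_to_mat)
  Ds <- lapply(obj$D, .list_to_mat)
  structure(list(F = Fs, D = Ds, comp = as.data.frame(obj$comp),
                 lambda = obj$lambda, mu = obj$mu,
                 noise_weight = obj$noise_weight,
                 means = obj$means, dims = obj$dims, time = obj$time,
                 Xnorm2 = obj$Xnorm2, psth = NULL, mset = NULL),
            class = "dpca")
}

#' Assemble a pipeline run configuration
#'
#' A plain serializable list of every knob the pipeline reads; all random
#' steps take their seed from here, so identical configurations give
#' identical results.
#'
#' @param input path to a long-format CSV trial tensor, or `NULL` to
#'   simulate data with [generate_population()].
#' @param sim_args arguments for the simulation when `input` is `NULL`.
#' @param q components per marginalization.
#' @param lambda fixed regularization strength, or `NULL` to select it by
#'   cross-validation.
#' @param cv_reps,cv_grid cross-validation settings (used when `lambda`
#'   is `NULL`).
#' @param seed integer seed for all stochastic steps.
#' @param out_dir output directory for artifacts.
#' @param verbose print stage progress.
#' @return a list of class `dpca_config`.
#' @export
run_config <- function(input = NULL, sim_args = list(), q = 10,
                       lambda = NULL, cv_reps = 10, cv_grid = NULL,
                       seed = 1L, out_dir = tempfile("dpca_run_"),
                       verbose = TRUE) {
  structure(list(input = input, sim_args = sim_args, q = q, lambda = lambda,
                 cv_reps = cv_reps, cv_grid = cv_grid, seed = as.integer(seed),
                 out_dir = out_dir, verbose = verbose),
            class = "dpca_config")
}

# small stable hash (FNV-1a over the JSON serialization) to stamp artifacts
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b %% 65536)    # 32-bit xor in 16-bit halves
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full dPCA pipeline
#'
#' Simulates or loads trial data, averages it into PSTHs, decomposes,
#' optionally selects the regularization strength by cross-validation,
#' fits dPCA, and writes the artifacts (model JSON, per-component variance
#' CSV, summary JSON) to the configured output directory. Any stage
#' failure aborts with a stage-tagged error.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the fitted model, the variance report and
#'   the paths of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "dpca_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  data <- stage("input", {
    if (is.null(config$input)) {
      say("simulating population (seed ", config$seed, ")")
      do.call(generate_population,
              c(config$sim_args, list(seed = config$seed)))$data
    } else {
      say("reading ", config$input)
      read_trial_tensor(config$input)
    }
  })
  psth <- stage("preprocess", compute_psths(data, center = TRUE))
  noise <- stage("preprocess", estimate_noise_covariance(data))
  lambda <- config$lambda
  cv <- NULL
  if (is.null(lambda)) {
    cv <- stage("crossval", {
      say("selecting lambda by cross-validation")
      grid <- if (is.null(config$cv_grid)) lambda_grid() else config$cv_grid
      select_lambda(data, grid = grid, n_reps = config$cv_reps,
                    q = config$q, seed = config$seed + 1L)
    })
    lambda <- cv$lambda_opt
    say("selected lambda = ", signif(lambda, 3))
  }
  model <- stage("fit", dpca_fit(psth, noise = noise, q = config$q,
                                 lambda = lambda))
  report <- stage("evaluate", explained_variance(model))
  sv <- stage("evaluate", signal_variance(noise, model$mset))

  paths <- list(model = file.path(config$out_dir, "model.json"),
                variance = file.path(config$out_dir, "variance.csv"),
                summary = file.path(config$out_dir, "summary.json"))
  stage("write", {
    dpca_save(model, paths$model)
    utils::write.csv(report$components, paths$variance, row.names = FALSE)
    summ <- list(config_hash = config_hash(config),
                 seed = config$seed,
                 lambda = lambda,
                 n_components = nrow(model$comp),
                 total_r2 = report$total_r2,
                 signal_fraction = sv$signal_fraction,
                 pie_percent = as.list(sv$pie_percent),
                 demixing_index_top =
                   as.numeric(demixing_index(.stack_D(model,
                     utils::head(model$comp, 5)), model$mset)),
                 package_version = as.character(utils::packageVersion("dpca")))
    jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA)
  })
  say("artifacts written to ", config$out_dir)
  invisible(list(model = model, variance = report, signal = sv, cv = cv,
                 paths = paths))
}
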