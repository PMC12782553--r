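#' Save a model snapshot
#'
#' Arrays are serialized as a compressed RDS container with a JSON sidecar
#' (`<path>.json`) recording the configuration, variant, seed and stored
#' cache locations, so a snapshot is self-describing.
#'
#' @param model A `barcode_model`.
#' @param path Output path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, compress = "gzip")
  sidecar <- list(
    package = "barcodeRNN",
    variant = model$variant,
    seed = model$seed,
    n_caches = length(model$traces),
    cache_locations = vapply(model$traces, `[[`, integer(1), "location"),
    config = unclass(model$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a model snapshot
#'
#' @param path Path written by [save_model()].
#' @return The `barcode_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "barcode_model"))
    stop("file does not contain a barcode model snapshot")
  model
}

#' Deterministic small fixture model
#'
#' Builds a reduced model (200 neurons, 20 states by default) with two
#' stored caches, for fast tests and examples.
#'
#' @param size `"small"` (N_x = 200, N_s = 20) or `"default"` (N_x = 1000,
#'   N_s = 100).
#' @param seed Integer seed.
#' @return A `barcode_model` with two caches stored.
#' @export
make_fixture <- function(size = c("small", "default"), seed = 1L) {
  size <- match.arg(size)
  cfg <- if (size == "small") {
    barcode_config(N_p = 400, N_x = 400, N_y = 400, N_s = 20, T_dyn = 100,
                   D = 24, M_hidden = 1600, rng_seed = seed)
  } else {
    barcode_config(N_p = 1000, N_x = 1000, N_y = 1000, rng_seed = seed) |>
      scale_config(1000)
  }
  model <- build_model(cfg, seed = seed)
  locs <- as.integer(round(cfg$N_s * c(0.25, 0.7))) + 1L
  for (l in locs) model <- store_cache(model, l)
  model
}

#' Assemble an experiment manifest
#'
#' @param name Experiment name: one of `"barcode_regimes"`,
#'   `"three_cache_task"`, `"correlation_profile"`, `"projection_sweep"`,
#'   `"ablation_contrast"`, `"feedforward_comparison"`.
#' @param cfg A [barcode_config()].
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @param variant Model variant.
#' @param spec Optional [task_spec()] for task experiments.
#' @param ... Extra experiment parameters stored in the manifest.
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(name, cfg, outdir, seed = cfg$rng_seed,
                                variant = "default", spec = NULL, ...) {
  known <- c("barcode_regimes", "three_cache_task", "correlation_profile",
             "projection_sweep", "ablation_contrast",
             "feedforward_comparison")
  if (!name %in% known)
    stop("unknown experiment '", name, "'; valid options: ",
         paste(known, collapse = ", "))
  man <- list(name = name, config = cfg, outdir = outdir,
              seed = as.integer(seed), variant = variant, spec = spec,
              extra = list(...),
              version = as.character(utils::packageVersion("barcodeRNN")))
  class(man) <- "experiment_manifest"
  man
}

write_manifest <- function(man) {
  dir.create(man$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(name = man$name, seed = man$seed, variant = man$variant,
              version = man$version, config = unclass(man$config),
              spec = if (!is.null(man$spec)) unclass(man$spec),
              extra = man$extra)
  jsonlite::write_json(out, file.path(man$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_table <- function(df, man, file) {
  utils::write.csv(df, file.path(man$outdir, file), row.names = FALSE)
}

#' Run a named experiment
#'
#' Writes the manifest first, then executes the experiment, writing tidy
#' CSV tables and a JSON summary of headline metrics into the output
#' directory. Identical manifests produce byte-identical tables.
#'
#' @param man An [experiment_manifest()].
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(man) {
  stopifnot(inherits(man, "experiment_manifest"))
  validate_config(man$config)
  write_manifest(man)
  cfg <- man$config
  summary <- switch(
    man$name,
    barcode_regimes = {
      sigmas <- man$extra$sigmas %||% c(1, 7, 20)
      n_seeds <- man$extra$n_seeds %||% 5L
      rows <- list()
      for (sg in sigmas) for (i in seq_len(n_seeds)) {
        model <- build_model(cfg, seed = man$seed + i, sigma = sg)
        X <- run_mode(model, seq_len(cfg$N_s), "recall", s_strength = 0)
        cc <- stats::cor(X)
        for (sep in c(1, 2, 4, 8, 16, 24)) {
          idx <- cbind(seq_len(cfg$N_s),
                       ((seq_len(cfg$N_s) - 1 + sep) %% cfg$N_s) + 1)
          rows[[length(rows) + 1L]] <- data.frame(
            sigma = sg, seed = i, separation = sep, corr = mean(cc[idx]))
        }
      }
      df <- do.call(rbind, rows)
      write_table(df, man, "regimes.csv")
      adj <- stats::aggregate(corr ~ sigma, df[df$separation == 1, ], mean)
      list(adjacent_correlation = stats::setNames(adj$corr,
                                                  paste0("sigma_", adj$sigma)))
    },
    three_cache_task = {
      spec <- man$spec %||% task_spec()
      factory <- make_ablation(man$extra$kind %||% "full", cfg)
      res <- run_three_cache_task(spec, cfg, factory, seed = man$seed)
      write_table(res$data, man, "task_queries.csv")
      pres <- summarize_task(res, "present")
      succ <- summarize_task(res, "success")
      write_table(pres, man, "cache_presence.csv")
      write_table(succ, man, "cache_location.csv")
      at_cache <- succ[succ$dist_nearest == 0 & succ$s == min(succ$s), ]
      list(mean_success_at_cache = mean(at_cache$p))
    },
    correlation_profile = {
      prof <- correlation_profile(
        cfg, n_experiments = man$extra$n_experiments %||% 20L,
        n_sites = man$extra$n_sites %||% 5L, seed = man$seed,
        variant = man$variant)
      write_table(as.data.frame(prof), man, "correlation_profile.csv")
      same <- prof$value[prof$condition == "cache_retrieval" &
                           prof$distance == 0]
      list(same_site_cache_retrieval = same,
           normalization = attr(prof, "normalization"))
    },
    projection_sweep = {
      model <- build_model(cfg, seed = man$seed, variant = "hybrid")
      dec <- code_projection(model,
                             r_values = man$extra$r_values %||%
                               seq(0, 1, by = 0.1))
      write_table(as.data.frame(dec), man, "projection.csv")
      pk <- function(cd) dec$r[dec$code == cd][
        which.max(dec$projection[dec$code == cd])]
      list(place_peak_r = pk("place"), predictive_peak_r = pk("predictive"),
           barcode_peak_r = pk("barcode"))
    },
    ablation_contrast = {
      spec <- man$spec %||% task_spec()
      kinds <- c("full", "place_only", "barcode_only")
      out <- lapply(kinds, function(k) {
        res <- run_three_cache_task(spec, cfg, make_ablation(k, cfg),
                                    seed = man$seed)
        cbind(kind = k, summarize_task(res, "present"))
      })
      df <- do.call(rbind, out)
      write_table(df, man, "ablation_presence.csv")
      list(kinds = kinds)
    },
    feedforward_comparison = {
      bank <- place_inputs(cfg)
      ff <- feedforward_model(cfg, man$seed)
      thetas <- man$extra$thetas %||% c(0.5, 0.2, 0.05)
      target <- man$extra$target_sparsity %||% 0.1
      rows <- lapply(thetas, function(th) {
        cfg2 <- cfg; cfg2$theta <- th
        bc <- feedforward_barcode(bank, ff, cfg2, target)
        cc <- stats::cor(t(bc))
        idx <- cbind(seq_len(cfg$N_s),
                     (seq_len(cfg$N_s) %% cfg$N_s) + 1)
        data.frame(theta = th, adjacent_corr = mean(cc[idx]))
      })
      df <- do.call(rbind, rows)
      write_table(df, man, "feedforward.csv")
      list(adjacent_corr = stats::setNames(df$adjacent_corr,
                                           paste0("theta_", df$theta)))
    })
  jsonlite::write_json(summary, file.path(man$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regenerate figures from experiment outputs
#'
#' Reads only the CSV tables produced by [run_experiment()] in `outdir` and
#' writes simple vector-graphics summaries (PDF) next to them.
#'
#' @param outdir Directory holding experiment outputs.
#' @return Paths of the figures written, invisibly.
#' @export
render_figures <- function(outdir) {
  written <- character(0)
  plot_to <- function(file, expr) {
    path <- file.path(outdir, file)
    grDevices::pdf(path, width = 6, height = 4)
    on.exit(grDevices::dev.off())
    expr
    written <<- c(written, path)
  }
  f <- file.path(outdir, "regimes.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    plot_to("fig_regimes.pdf", {
      agg <- stats::aggregate(corr ~ sigma + separation, df, mean)
      plot(NA, xlim = range(agg$separation), ylim = c(-0.2, 1),
           xlab = "separation (states)", ylab = "correlation")
      for (sg in unique(agg$sigma)) {
        g <- agg[agg$sigma == sg, ]
        graphics::lines(g$separation, g$corr, type = "b",
                        col = which(unique(agg$sigma) == sg))
      }
      graphics::legend("topright", legend = paste("sigma", unique(agg$sigma)),
                       col = seq_along(unique(agg$sigma)), lty = 1)
    })
  }
  f <- file.path(outdir, "correlation_profile.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    plot_to("fig_profile.pdf", {
      plot(NA, xlim = range(df$distance), ylim = range(c(df$lo, df$hi)),
           xlab = "site distance", ylab = "normalized correlation")
      for (cd in unique(df$condition)) {
        g <- df[df$condition == cd, ]
        graphics::lines(g$distance, g$value, type = "b",
                        col = which(unique(df$condition) == cd))
      }
      graphics::legend("topright", legend = unique(df$condition),
                       col = seq_along(unique(df$condition)), lty = 1)
    })
  }
  f <- file.path(outdir, "projection.csv")
  if (file.exists(f)) {
    df <- utils::read.csv(f)
    plot_to("fig_projection.pdf", {
      plot(NA, xlim = c(0, 1), ylim = c(0, 1.05),
           xlab = "recurrence gain r", ylab = "projection (max-normalized)")
      for (cd in unique(df$code)) {
        g <- df[df$code == cd, ]
        graphics::lines(g$r, g$projection, type = "b",
                        col = which(unique(df$code) == cd))
      }
      graphics::legend("top", legend = unique(df$code),
                       col = seq_along(unique(df$code)), lty = 1)
    })
  }
  invisible(written)
}
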