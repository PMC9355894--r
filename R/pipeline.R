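## Pipeline driver behind the command-line interface. Each subcommand is a
## thin wrapper over the package functions; every artifact embeds the
## config hash and seeds so results are traceable.

artifact_header <- function(config, seed = NULL) {
  h <- list(tool = "iphase", version = as.character(utils::packageVersion("iphase")),
            config_hash = config_hash(config))
  if (!is.null(seed)) h$seed <- seed
  h
}

#' Run one pipeline stage
#'
#' Subcommands: \code{simulate} (one Monte Carlo scenario run),
#' \code{ratio} (top/bottom ratio over repeats), \code{synth} (write a
#' synthetic MRC ensemble), \code{measure} (measure MRC stacks to CSV) and
#' \code{analyze} (ensemble statistics and comparison from a measurement
#' CSV). Outputs are JSON or CSV files carrying the config hash and seeds.
#'
#' @param config An \code{iphase_config}.
#' @param subcommand One of simulate, ratio, synth, measure, analyze.
#' @param args Named list of stage arguments (see details of each wrapped
#'   function); \code{out} is the output path where applicable.
#' @return The output artifact path (or the result object), invisibly.
#' @export
run_pipeline <- function(config, subcommand, args = list()) {
  arg <- function(name, default = NULL) {
    if (!is.null(args[[name]])) args[[name]] else default
  }
  sim <- config$simulation
  switch(subcommand,
    simulate = {
      stack <- build_stack(arg("orientation", "top"), config)
      res <- run_scenario(stack, config_beam(config),
                          as.integer(arg("scenario", 1)),
                          arg("n", sim$n_electrons),
                          arg("seed", sim$seed))
      out <- arg("out", "counts.json")
      jsonlite::write_json(c(artifact_header(config, res$seed),
                             unclass(res)),
                           out, auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    ratio = {
      res <- top_bottom_ratio(config, as.integer(arg("scenario", 1)),
                              arg("n", sim$n_electrons),
                              arg("repeats", sim$n_repeats),
                              arg("seed", sim$seed))
      out <- arg("out", "ratio.json")
      keep <- res[c("scenario", "ratio", "sd", "n_repeats", "n_electrons",
                    "seeds", "mean_top", "mean_bottom")]
      jsonlite::write_json(c(artifact_header(config), keep), out,
                           auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    synth = {
      out_dir <- arg("out", "synth")
      render_ensemble(arg("n_top", 91), arg("n_bottom", 92),
                      arg("true_ratio", 1.0), config,
                      arg("seed", sim$seed), out_dir = out_dir)
      invisible(out_dir)
    },
    measure = {
      in_dir <- arg("in")
      if (is.null(in_dir)) stop("measure needs args$in (ensemble directory)")
      truth <- utils::read.csv(file.path(in_dir, "truth.csv"))
      mp <- config$measurement
      rows <- lapply(seq_len(nrow(truth)), function(i) {
        mrc <- read_mrc(file.path(in_dir,
                                  paste0(truth$particle_id[i], ".mrc")))
        series <- structure(list(frames = mrc$data,
                                 defocus_list = default_defocus_grid(config),
                                 pixel_size = mrc$pixel_size),
                            class = "defocus_series")
        if (length(series$frames) != length(series$defocus_list))
          stop("frame count does not match the configured defocus grid")
        m <- measure_series(series, d_target = mp$d_target_angstrom,
                            d_tol = mp$d_tol_angstrom)
        data.frame(particle_id = truth$particle_id[i],
                   side = truth$side[i],
                   defocus_at_max = m$defocus_at_max,
                   representative_power = m$representative,
                   mean_counts = mean(mrc$data[[1]]))
      })
      out <- arg("out", "measurements.csv")
      utils::write.csv(do.call(rbind, rows), out, row.names = FALSE)
      invisible(out)
    },
    analyze = {
      csv <- arg("in")
      if (is.null(csv)) stop("analyze needs args$in (measurement CSV)")
      df <- utils::read.csv(csv)
      cmp <- compare_sides(
        df$representative_power[df$side == "top"],
        df$representative_power[df$side == "bottom"],
        simulated = arg("simulated"))
      out <- arg("out", "analysis.json")
      payload <- c(artifact_header(config), list(
        stats_top = unclass(cmp$stats_top),
        stats_bottom = unclass(cmp$stats_bottom),
        t_statistic = cmp$t_statistic, p_value = cmp$p_value,
        ratio = cmp$ratio, ratio_sd = cmp$ratio_sd))
      if (!is.null(cmp$exclusions))
        payload$sigma_exclusion <- as.list(cmp$exclusions)
      jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA)
      invisible(out)
    },
    stop("unknown subcommand: ", subcommand,
         " (expected simulate, ratio, synth, measure or analyze)"))
}
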