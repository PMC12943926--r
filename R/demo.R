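#' Evaluate a model on labelled clouds
#'
#' Runs prediction on each block and scores it against the blocks' own
#' labels with the full metric suite.
#'
#' @param model a trained `its_model`.
#' @param clouds list of labelled `forest_cloud`s.
#' @return an `eval_report` (see [evaluate_run()]).
#' @export
evaluate_model <- function(model, clouds) {
  preds <- lapply(clouds, function(cl) predict_instances(model, cl)$cloud)
  evaluate_run(preds, clouds)
}

#' Single-command end-to-end demonstration
#'
#' Generates a small synthetic leaf-off dataset, trains the desk-profile
#' model on it, evaluates on the training split and returns the full metric
#' report. Everything is driven by one seed.
#'
#' @param seed master seed.
#' @param n_blocks number of synthetic training blocks.
#' @param iters optimizer steps (default: desk profile setting).
#' @param out_dir optional directory for the blocks, checkpoint, resolved
#'   config and report JSON.
#' @param quiet suppress progress output.
#' @return list with `report` (an `eval_report`), `model`, `blocks` and the
#'   training `log`.
#' @export
end_to_end_demo <- function(seed = 1L, n_blocks = 4L, iters = NULL,
                            out_dir = NULL, quiet = FALSE) {
  cfg <- desk_profile(seed)
  blocks <- lapply(seq_len(n_blocks), function(i) {
    pp <- cfg$synth$plot
    pp$seed <- derive_seed(seed, i)
    generate_plot(pp, cfg$synth$tree)
  })
  model <- init_model(cfg, seed = derive_seed(seed, 9000L))
  model <- train_model(model, blocks, iters = iters,
                       log_every = if (quiet) 0L else 25L)
  report <- evaluate_model(model, blocks)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (i in seq_along(blocks))
      write_point_cloud(blocks[[i]], file.path(out_dir, sprintf("block_%03d.ply", i)))
    save_checkpoint(model, file.path(out_dir, "model.rds"))
    write_config(cfg, file.path(out_dir, "config.yaml"))
    evaluate_run(lapply(blocks, function(b) predict_instances(model, b)$cloud),
                 blocks, out_json = file.path(out_dir, "report.json"))
  }
  if (!quiet) print(report)
  list(report = report, model = model, blocks = blocks, log = attr(model, "log"))
}

#' Write / read a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_config`: the path, invisibly; `read_config`: a
#'   `run_config` with file values overlaid on the defaults.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (isTRUE(all.equal(y$backbone$width_multiplier, 0.25))) desk_profile()
          else run_config()
  overlay <- function(b, o) {
    for (nm in names(o))
      b[[nm]] <- if (is.list(o[[nm]]) && is.list(b[[nm]])) overlay(b[[nm]], o[[nm]])
                 else o[[nm]]
    b
  }
  structure(overlay(unclass(base), y), class = "run_config")
}
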