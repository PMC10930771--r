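# YAML configuration surface: one file with model / attention / train /
# data sections, mapped onto magnet_config() and train_config().

#' Default configuration as a nested list
#'
#' @param desk if `TRUE`, the desk-scale profile (small networks, short
#'   schedule) used by the bundled tests; otherwise the reference profile.
#' @export
default_config <- function(desk = FALSE) {
  mc <- if (desk) desk_config() else magnet_config()
  tc <- if (desk) desk_train_config() else train_config()
  list(
    model = list(layers = mc$L, patches_per_layer = mc$P,
                 frozen_patch = mc$frozen_patch, backbone = mc$backbone,
                 backbone_widths = mc$backbone_widths,
                 gru_hidden = mc$gru_hidden, head_sizes = mc$head_sizes),
    attention = list(branch_width = mc$branch_width, k_aux = mc$k_aux,
                     noise_sd = mc$noise_sd, grey_tau = mc$grey_tau),
    train = list(lr = tc$lr, epochs = tc$epochs, batch_size = tc$batch_size,
                 seed = tc$seed, augment = tc$augment),
    data = list(level0_side = 2048L, mmax = 6L, lesion_scale = "micro")
  )
}

#' Load a YAML config, filling unset keys from the desk defaults
#' @param path YAML file.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(desk = TRUE), cfg)
}

config_to_model <- function(cfg) {
  magnet_config(layers = cfg$model$layers,
                patches_per_layer = cfg$model$patches_per_layer,
                frozen_patch = cfg$model$frozen_patch,
                backbone = cfg$model$backbone,
                backbone_widths = cfg$model$backbone_widths,
                branch_width = cfg$attention$branch_width,
                gru_hidden = cfg$model$gru_hidden,
                head_sizes = cfg$model$head_sizes,
                k_aux = cfg$attention$k_aux,
                noise_sd = cfg$attention$noise_sd,
                grey_tau = cfg$attention$grey_tau)
}

config_to_train <- function(cfg) {
  train_config(lr = cfg$train$lr, epochs = cfg$train$epochs,
               batch_size = cfg$train$batch_size, seed = cfg$train$seed,
               augment = cfg$train$augment)
}

#' Command-line interface
#'
#' Subcommands: `synth` (generate a dataset), `train`, `eval`, `trace`.
#' Installed as `inst/cli/magnet.R`; run with
#' `Rscript -e 'magnet::magnet_cli()' <cmd> ...` or via the installed
#' script.
#'
#' @param argv character vector of arguments (defaults to the command line).
#' @export
magnet_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    cat("usage: magnet <synth|train|eval|trace> [options]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  args <- argv[-1]
  op <- function(...) optparse::OptionParser(option_list = list(...),
                                             prog = paste("magnet", cmd))
  o <- optparse::make_option
  switch(cmd,
    synth = {
      p <- op(o("--n", type = "integer", default = 10L),
              o("--out", type = "character"),
              o("--seed", type = "integer", default = 1L),
              o("--lesion-scale", type = "character", default = "micro",
                dest = "lesion_scale"))
      a <- optparse::parse_args(p, args)
      man <- generate_dataset(a$n, a$out, seed = a$seed,
                              lesion_scale = a$lesion_scale)
      cat(sprintf("wrote %d slides to %s\n", nrow(man), a$out))
    },
    train = {
      p <- op(o("--config", type = "character", default = NULL),
              o("--data", type = "character"),
              o("--out", type = "character", default = "run"))
      a <- optparse::parse_args(p, args)
      cfg <- if (is.null(a$config)) default_config(desk = TRUE)
             else load_config(a$config)
      man <- read_manifest(a$data)
      fit <- magnet_train(config_to_model(cfg),
                          man[man$split == "train", ],
                          man[man$split == "val", ],
                          config_to_train(cfg), out_dir = a$out,
                          verbose = TRUE)
      cat(sprintf("best validation AUROC %.3f (epoch %d); run dir: %s\n",
                  max(fit$history$val_auroc, na.rm = TRUE), fit$best_epoch,
                  a$out))
    },
    eval = {
      p <- op(o("--weights", type = "character"),
              o("--data", type = "character"),
              o("--split", type = "character", default = NULL),
              o("--by-stratum", type = "character", default = NULL,
                dest = "by_stratum"),
              o("--out", type = "character", default = NULL))
      a <- optparse::parse_args(p, args)
      model <- load_checkpoint(a$weights)
      man <- read_manifest(a$data)
      if (!is.null(a$split)) man <- man[man$split == a$split, ]
      rep <- magnet_evaluate(model, man, by = a$by_stratum)
      print(rep)
      if (!is.null(a$out))
        jsonlite::write_json(rep[c("auroc", "accuracy", "n")], a$out,
                             auto_unbox = TRUE, digits = NA)
    },
    trace = {
      p <- op(o("--weights", type = "character"),
              o("--slide", type = "character"),
              o("--out", type = "character", default = "trace.png"))
      a <- optparse::parse_args(p, args)
      model <- load_checkpoint(a$weights)
      pyr <- read_pyramid(a$slide)
      fwd <- magnet_forward(model, pyr)
      render_trace(fwd$trace, pyr, a$out)
      cat(sprintf("y_hat = %.3f; trace written to %s\n", fwd$y_hat, a$out))
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
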