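# Persistence: datasets and model checkpoints as RDS containers paired with
# JSON manifests (shapes and metadata), plus CSV/TSV exports for histories,
# reports and confusion matrices.

write_manifest <- function(path, command, extra = list()) {
  man <- c(list(command = command,
                package_version = as.character(utils::packageVersion("tanet")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(man, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(man)
}

#' Save / load a dataset
#'
#' Stores any dataset list (raw EEG, feature tensors, segments) as RDS with
#' a JSON sidecar manifest recording the shapes.
#'
#' @param x dataset object.
#' @param path file path (`.rds` recommended).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the object.
#' @export
save_dataset <- function(x, path) {
  saveRDS(x, path)
  shapes <- lapply(Filter(function(e) !is.null(dim(e)), unclass(x)), dim)
  write_manifest(path, "save_dataset",
                 list(class = class(x)[1], shapes = shapes))
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) readRDS(path)

#' Save / load a model checkpoint
#'
#' Serialises configuration, parameters and batch-normalisation running
#' statistics; the JSON manifest maps every parameter name to its shape.
#' A load/save round trip reproduces bit-identical forward passes.
#'
#' @param model a `tanet_model`.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `tanet_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(config = model$config, params = as.list(model$params),
              state = as.list(model$state))
  saveRDS(obj, path)
  write_manifest(path, "save_checkpoint",
                 list(n_parameters = count_trainable_parameters(model),
                      shapes = lapply(obj$params, function(p) dim(p) %||% length(p))))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- list(config = obj$config,
                params = list2env(obj$params, new.env(parent = emptyenv())),
                state = list2env(obj$state, new.env(parent = emptyenv())))
  class(model) <- "tanet_model"
  model
}

#' Export an evaluation report
#'
#' Writes the scalar metrics as JSON and the confusion matrix as TSV.
#'
#' @param report an `evaluation_report` or [aggregate_runs()] result.
#' @param path base path; `.json` and `.confusion.tsv` are appended.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  scal <- report[setdiff(names(report), c("confusion", "per_run"))]
  jsonlite::write_json(scal, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cm <- report$confusion
  if (!is.null(cm)) {
    utils::write.table(cm, paste0(path, ".confusion.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
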