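# Plain-text persistence. Maps and holograms are stored as a small
# commented header (shape, pitch) followed by whitespace-delimited rows;
# configs and model checkpoints as JSON.

#' Write a 2D map to a plain-text file
#'
#' @param values numeric matrix.
#' @param path output file.
#' @param pixel_pitch pixel pitch (um) recorded in the header.
#' @export
write_map <- function(values, path, pixel_pitch) {
  values <- as.matrix(values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# holocell map",
               sprintf("# shape: %d %d", nrow(values), ncol(values)),
               sprintf("# pitch_um: %.10g", pixel_pitch)), con)
  utils::write.table(values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a map written by [write_map()]
#'
#' @param path input file.
#' @return numeric matrix with a `pixel_pitch` attribute.
#' @export
read_map <- function(path) {
  header <- readLines(path, n = 3L)
  pitch <- as.numeric(sub("# pitch_um: ", "", header[3L]))
  shape <- as.integer(strsplit(sub("# shape: ", "", header[2L]), " ")[[1L]])
  values <- as.matrix(utils::read.table(path, skip = 3L))
  dimnames(values) <- NULL
  stopifnot(identical(dim(values), shape))
  attr(values, "pixel_pitch") <- pitch
  values
}

#' Write an optics configuration as JSON
#' @param config an [optics_config].
#' @param path output file.
#' @export
write_optics_config <- function(config, path) {
  stopifnot(inherits(config, "optics_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an optics configuration written by [write_optics_config()]
#' @param path input file.
#' @return an [optics_config].
#' @export
read_optics_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(optics_config, x)
}

#' Save a trained unwrapper model as JSON
#'
#' Serializes the weights, the architecture spec, the channel normalization
#' constants and the training distance, so a checkpoint restores to a
#' functionally identical model.
#'
#' @param net an `unwrap_net`.
#' @param path output file.
#' @export
save_unwrapper <- function(net, path) {
  stopifnot(inherits(net, "unwrap_net"))
  payload <- list(
    spec = unclass(net$spec),
    norm = net$norm,
    training_Z = net$training_Z,
    trained = net$trained,
    layers = lapply(net$layers, function(l) {
      list(W = as.vector(l$W), W_dim = dim(l$W), b = l$b,
           gamma = l$gamma, beta = l$beta,
           run_mean = l$run_mean, run_var = l$run_var)
    }),
    final = list(W = as.vector(net$final$W), W_dim = dim(net$final$W),
                 b = net$final$b)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an unwrapper model saved by [save_unwrapper()]
#' @param path input file.
#' @return an `unwrap_net`.
#' @export
load_unwrapper <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(network_spec, p$spec[c("n_blocks", "kernel_size",
                                         "n_features", "scale")])
  layers <- lapply(seq_len(spec$n_blocks), function(i) {
    l <- if (is.data.frame(p$layers)) {
      lapply(p$layers, function(col) col[[i]])
    } else {
      p$layers[[i]]
    }
    list(W = matrix(unlist(l$W), nrow = l$W_dim[1], ncol = l$W_dim[2]),
         b = as.numeric(l$b), gamma = as.numeric(l$gamma),
         beta = as.numeric(l$beta), run_mean = as.numeric(l$run_mean),
         run_var = as.numeric(l$run_var))
  })
  final <- list(W = matrix(unlist(p$final$W), nrow = p$final$W_dim[1],
                           ncol = p$final$W_dim[2]),
                b = as.numeric(p$final$b))
  structure(list(spec = spec, layers = layers, final = final,
                 norm = as.list(p$norm), training_Z = p$training_Z,
                 trained = isTRUE(p$trained), loss_history = numeric(0)),
            class = "unwrap_net")
}
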