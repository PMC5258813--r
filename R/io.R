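#' Write / read a multi-channel field as 16-bit TIFF
#'
#' Channels are stored as pages of one multi-page 16-bit unsigned TIFF in a
#' fixed order (`nuclear`, `x`, `y`); integer camera counts are preserved
#' exactly.
#'
#' @param field An `image_field`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(field, path) {
  pages <- lapply(field$channels, function(ch) ch / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param channel_names Channel names to assign to the pages on read.
#' @param bit_depth Camera bit depth recorded on the returned field.
#' @export
read_field_tiff <- function(path, channel_names = c("nuclear", "x", "y"),
                            bit_depth = 12L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) != length(channel_names))
    abort(sprintf("expected %d pages, found %d", length(channel_names),
                  length(pages)))
  channels <- lapply(pages, function(p) {
    m <- matrix(as.integer(round(p)), nrow(p), ncol(p))
    m
  })
  names(channels) <- channel_names
  structure(list(channels = channels, bit_depth = as.integer(bit_depth)),
            class = "image_field")
}

#' Write / read a label mask as 16-bit TIFF
#'
#' @param labels Integer label matrix (values must fit in 16 bits).
#' @param path TIFF path.
#' @return `path` (write) or the integer label matrix (read).
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) abort("more than 65535 labels cannot be stored in 16-bit TIFF")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  p <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(round(p)), nrow(p), ncol(p))
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$phenotype_fractions <- as.list(x$phenotype_fractions)
  x$expression_params <- as.data.frame(x$expression_params)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  ep <- as_tibble(lapply(x$expression_params, unlist))
  do.call(sim_config, c(
    list(field_shape = unlist(x$field_shape),
         colony_radius_range = unlist(x$colony_radius_range),
         phenotype_fractions = unlist(x$phenotype_fractions),
         edge_phenotypes = unlist(x$edge_phenotypes),
         expression_params = ep),
    x[setdiff(names(x), c("field_shape", "colony_radius_range",
                          "phenotype_fractions", "edge_phenotypes",
                          "expression_params"))]))
}
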