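#' Published 30-map experimental benchmark
#'
#' Loads the packaged benchmark of thirty experimental EMDB density maps:
#' the author-claimed resolution of each map and the global resolution
#' class assigned to it by the published dense-network and 3D-CNN
#' classifiers. The claimed resolutions span ten high- (1.6-2.9 A), ten
#' medium- (6.0-8.0 A) and ten low-resolution (11.0-14.8 A) maps. Feeding
#' these columns through [confusionMatrix3()], [combinedAgreement()] and
#' [classMetrics()] reproduces the published worked-example metrics.
#'
#' @return data.frame with columns \code{emdb_id},
#'   \code{published_resolution}, \code{dnn_predicted},
#'   \code{cnn_predicted}, plus a derived \code{published_class}.
#' @examples
#' b <- experimentalBenchmark()
#' combinedAgreement(confusionMatrix3(b$published_class, b$dnn_predicted))
#' @export
experimentalBenchmark <- function() {
  path <- system.file("extdata", "experimental_classifications.csv",
                      package = "cryores", mustWork = TRUE)
  b <- utils::read.csv(path, stringsAsFactors = FALSE)
  b$published_class <- threeClassLabel(b$published_resolution)
  b
}
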