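#' Feature catalogs
#'
#' A feature catalog is an ordered table of feature specifications that
#' defines exactly which features [extract_features()] computes and in which
#' order. Each entry has a canonical `name` (e.g. `Wavelet_LHH_GLCM_correl1`),
#' a `family` (`Stats`, `Shape`, `GLCM`, `GLRLM`, `GLSZM`, `GLDZM`, `NGLDM`,
#' `NGTDM`), an image `channel` (`original` or one of the eight wavelet bands
#' `LLL` ... `HHH`) and the within-family `feature` key.
#'
#' The default catalog shipped with the package has 370 entries: 7
#' first-order statistics, 19 shape/size features, 65 texture features on the
#' original image distributed over the six matrix families, and 279
#' statistics/texture features on the wavelet sub-bands. The catalog is a
#' data file (YAML), so alternative feature sets can be loaded without
#' touching code.
#'
#' @param path Path to a catalog YAML file.
#' @return A tibble with columns `name`, `family`, `channel`, `feature`, and
#'   attributes `catalog_version`, `n_bins`, `wavelet` carrying the
#'   extraction parameters the catalog was built for.
#' @export
read_catalog <- function(path) {
  y <- yaml::read_yaml(path)
  feats <- dplyr::bind_rows(lapply(y$features, tibble::as_tibble))
  required <- c("name", "family", "channel", "feature")
  if (!all(required %in% names(feats))) {
    stop("catalog entries need fields: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(feats$name)) {
    stop("catalog feature names must be unique", call. = FALSE)
  }
  bad <- setdiff(feats$channel, c("original", wavelet_band_names()))
  if (length(bad) > 0) {
    stop("unknown channel(s) in catalog: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  attr(feats, "catalog_version") <- y$version %||% "unversioned"
  attr(feats, "n_bins") <- y$discretization$n_bins %||% 32
  attr(feats, "wavelet") <- y$wavelet %||% "coif1"
  feats
}

#' @rdname read_catalog
#' @export
default_catalog <- function() {
  if (is.null(the$default_catalog)) {
    path <- system.file("extdata", "default_catalog.yaml", package = "lesionrad")
    the$default_catalog <- read_catalog(path)
  }
  the$default_catalog
}

# package-local cache
the <- new.env(parent = emptyenv())

wavelet_band_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' Tabulate a catalog by feature group
#'
#' Counts catalog entries in the four groups used to describe the feature
#' space: first-order statistics, shape, original-image texture, and
#' wavelet-channel features.
#'
#' @param catalog A catalog tibble from [read_catalog()].
#' @return A tibble with columns `group` and `n`.
#' @export
catalog_group_counts <- function(catalog = default_catalog()) {
  grp <- dplyr::case_when(
    catalog$family == "Shape" ~ "shape",
    catalog$channel != "original" ~ "wavelet",
    catalog$family == "Stats" ~ "first_order",
    TRUE ~ "texture"
  )
  tibble::tibble(group = c("first_order", "shape", "texture", "wavelet")) |>
    dplyr::left_join(tibble::tibble(group = grp) |> dplyr::count(.data$group),
                     by = "group") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
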