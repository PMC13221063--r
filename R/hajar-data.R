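#' Published site metrics from the Hajar Mountain killifish survey
#'
#' The per-site summary values published for the 12 surveyed wadi sites in
#' northern Oman (Darsait D1-D3, Al Amirat A1-A3, Surur/Fanja/Al Khoud
#' K1-K3, Ain Wadhah AW1-AW3): composite HSI of each site, its published
#' suitability class label, and the alpha diversity metrics (Shannon,
#' Gini-Simpson, Pielou evenness) of the local fish community. These values
#' are inputs for reproducing the published trade-off statistics (the
#' negative HSI-diversity correlations) and for exercising the classifier
#' against the published thresholds (preset `"hajar"`, see
#' [classify_suitability()]).
#'
#' Note the published table is internally inconsistent for two sites: K2
#' (HSI 0.724) carries the label of the top threshold interval and AW1
#' (0.587) that of the interval above its value. The `published_class`
#' column reproduces the labels as printed; threshold-derived labels can be
#' recomputed with [classify_suitability()].
#'
#' @return data.frame with columns `site`, `shannon`, `simpson`,
#'   `evenness`, `hsi`, `published_class`.
#' @export
hajar_metrics <- function() {
  data.frame(
    site = c("A1", "A2", "A3", "AW1", "AW2", "AW3",
             "D1", "D2", "D3", "K1", "K2", "K3"),
    shannon = c(1.213, 0.871, 0.034, 1.184, 0.837, 0.942,
                0.133, 0.185, 0.678, 0.234, 0.533, 0.435),
    simpson = c(0.665, 0.441, 0.010, 0.660, 0.485, 0.501,
                0.050, 0.076, 0.381, 0.095, 0.268, 0.203),
    evenness = c(0.875, 0.629, 0.031, 0.854, 0.604, 0.680,
                 0.121, 0.134, 0.617, 0.169, 0.384, 0.314),
    hsi = c(0.584, 0.490, 0.945, 0.587, 0.526, 0.443,
            0.781, 0.581, 0.496, 0.635, 0.724, 0.433),
    published_class = c("Moderately Suitable", "Less Suitable",
                        "Highly Suitable", "Suitable",
                        "Moderately Suitable", "Unsuitable",
                        "Highly Suitable", "Moderately Suitable",
                        "Less Suitable", "Suitable", "Highly Suitable",
                        "Unsuitable"))
}

#' Published confusion counts from the Hajar Mountain HSI validation
#'
#' The 2x2 classification outcome published for the 12-site HSI validation:
#' 4 true positives, 6 true negatives, 2 false negatives, 0 false
#' positives. Feeding these counts to [confusion_metrics()] reproduces the
#' published battery (sensitivity 66.7%, specificity 100%, accuracy 83.3%,
#' precision 100%, F1 80.0%, TSS 0.667).
#'
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
hajar_confusion <- function() c(tp = 4L, fp = 0L, tn = 6L, fn = 2L)

#' Published conservation-gap inputs for Oman's wadi network
#'
#' Current protection rates of high-suitability habitat for the two
#' killifish species (0.31% for A. kruppi, 1.34% for A. stoliczkanus), the
#' national (7.5% by 2040) and CBD 30x30 (30%) protection targets, and the
#' protected stream counts by wadi-density class (high 58, medium 427, low
#' 1,731 of 2,216 protected streams).
#'
#' @return list with `rates` (named numeric, percent), `targets` (named
#'   numeric, percent), `protected_streams` (named integer).
#' @export
hajar_gap_inputs <- function() {
  list(rates = c(kruppi = 0.31, stoliczkanus = 1.34),
       targets = c(national_2040 = 7.5, cbd_30x30 = 30),
       protected_streams = c(high = 58L, medium = 427L, low = 1731L))
}
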