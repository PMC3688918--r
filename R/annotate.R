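#' Default adduct and neutral-loss rules for positive-mode ESI
#'
#' Ion species considered when matching observed m/z values to candidate
#' compounds: the protonated molecule, the sodium adduct, and protonated
#' species after each configured neutral loss (seeded with the formic-acid
#' loss CH2O2 seen for in-source fragments). Proton and sodium cation
#' masses are 1.00728 and 22.98922 Da.
#'
#' @param neutral_losses named numeric vector of neutral-loss masses in Da
#'   (default `c(CH2O2 = 46.00548)`).
#' @return data.frame with columns `adduct` and `shift` (Da added to the
#'   monoisotopic mass).
#' @export
adduct_rules <- function(neutral_losses = c(CH2O2 = 46.00548)) {
  proton <- 1.00728
  sodium <- 22.98922
  out <- data.frame(adduct = c("[M+H]+", "[M+Na]+"),
                    shift = c(proton, sodium),
                    stringsAsFactors = FALSE)
  if (length(neutral_losses)) {
    loss <- data.frame(
      adduct = sprintf("[M+H-%s]+", names(neutral_losses)),
      shift = proton - as.numeric(neutral_losses),
      stringsAsFactors = FALSE)
    out <- rbind(out, loss)
  }
  out
}

#' Putative annotation of features by accurate mass
#'
#' Matches observed feature m/z values against theoretical m/z of each
#' (compound, ion species) pair within a mass tolerance in mDa, reporting
#' the signed error of every match. Features matching nothing are listed
#' as unidentified. Shrinking the tolerance can only remove matches.
#'
#' @param features data.frame with columns `feature_id` and `mz` (a
#'   [feature_matrix]'s `$features` works directly).
#' @param compounds data.frame with columns `name` and
#'   `monoisotopic_mass` (Da).
#' @param tol_mda mass tolerance in mDa (default 5).
#' @param adducts adduct/loss rule table from [adduct_rules()].
#' @return List with `matches` (data.frame: feature_id, mz, compound,
#'   adduct, mz_theoretical, delta_mda) and `unidentified` (feature ids
#'   with no match).
#' @export
annotate_features <- function(features, compounds, tol_mda = 5,
                              adducts = adduct_rules()) {
  if (inherits(features, "feature_matrix")) features <- features$features
  stopifnot(tol_mda > 0, all(c("feature_id", "mz") %in% names(features)),
            all(c("name", "monoisotopic_mass") %in% names(compounds)),
            all(compounds$monoisotopic_mass > 0))
  rows <- list()
  for (ci in seq_len(nrow(compounds))) {
    for (ai in seq_len(nrow(adducts))) {
      theo <- compounds$monoisotopic_mass[ci] + adducts$shift[ai]
      delta <- (features$mz - theo) * 1000  # mDa
      hit <- which(abs(delta) <= tol_mda)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = features$feature_id[hit],
          mz = features$mz[hit],
          compound = compounds$name[ci],
          adduct = adducts$adduct[ai],
          mz_theoretical = theo,
          delta_mda = delta[hit],
          stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_id = character(0), mz = numeric(0),
               compound = character(0), adduct = character(0),
               mz_theoretical = numeric(0), delta_mda = numeric(0))
  rownames(matches) <- NULL
  list(matches = matches,
       unidentified = setdiff(features$feature_id, matches$feature_id))
}
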