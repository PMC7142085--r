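# Residue property scales. Numeric tables ship as an editable TSV in
# inst/extdata/property_scales.tsv; each scale carries a provenance note
# naming the literature scale it mirrors.

SCALE_PROVENANCE <- c(
  aromaticity = "binary indicator of the aromatic residues F, W, Y, H",
  polarity = "Zimmerman, Eliezer & Simha (1968) polarity",
  charge = "net side-chain charge at pH 7, binary +/-1 (H treated neutral)",
  hydrophobicity = "Kyte & Doolittle (1982) hydropathy",
  flexibility = "Bhaskaran & Ponnuswamy (1988) average flexibility",
  exposure = "sign-flipped Janin (1979) interior-to-surface transfer energy (higher = more exposed)",
  beta_frequency = "Chou & Fasman (1978) beta-sheet conformational propensity",
  coil_frequency = "Chou & Fasman (1978) turn propensity, as a coil/turn stand-in",
  disorder_propensity = "TOP-IDP-style disorder propensity (Campen et al. 2008 ordering)",
  order_propensity = "negated disorder propensity (order-promoting residues positive)",
  bulkiness = "Zimmerman, Eliezer & Simha (1968) bulkiness"
)

scales_path <- function() {
  p <- system.file("extdata", "property_scales.tsv", package = "glycolocale")
  if (!nzchar(p)) {
    # during in-source development (pkgload) system.file resolves inst/ itself
    abort("property_scales.tsv not found in the installed package")
  }
  p
}

#' Built-in residue property scales
#'
#' Returns the package's residue property scales: aromaticity, polarity, net
#' charge at pH 7, hydrophobicity, flexibility, surface exposure, beta-sheet
#' frequency, coil/turn frequency, disorder propensity, order propensity and
#' bulkiness. Values are read from the editable table
#' `inst/extdata/property_scales.tsv`; each scale carries a `provenance` note
#' naming the literature scale it mirrors.
#'
#' @param path Optional path to an alternative scale table with the same
#'   layout (column `aa` plus one numeric column per scale).
#' @return A named list; each element is a list with `name`, `provenance` and
#'   `values` (named numeric vector over the 20 standard residues).
#' @export
#' @examples
#' sc <- builtin_scales()
#' sc$hydrophobicity$values[["W"]]
builtin_scales <- function(path = NULL) {
  path <- path %||% scales_path()
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"aa" %in% names(tab)) abort("Scale table must have an 'aa' column")
  if (!setequal(tab$aa, AA20)) {
    abort("Scale table must cover exactly the 20 standard amino acids")
  }
  scale_names <- setdiff(names(tab), "aa")
  out <- lapply(scale_names, function(nm) {
    v <- setNames(tab[[nm]], tab$aa)[AA20]
    list(name = nm, provenance = unname(SCALE_PROVENANCE[nm] %|NA|% "user-supplied scale"),
         values = v)
  })
  names(out) <- scale_names
  if ("disorder_propensity" %in% scale_names && !"order_propensity" %in% scale_names) {
    v <- -out$disorder_propensity$values
    out$order_propensity <- list(
      name = "order_propensity",
      provenance = unname(SCALE_PROVENANCE["order_propensity"]),
      values = v
    )
  }
  out
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
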