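#' Construct a molecular state label token
#'
#' A state label identifies a distinguishable molecular subpopulation by four
#' categorical attributes: species, activation state, bound partner and
#' compartment. Count time series columns are named by these tokens, e.g.
#' \code{"MEK.inactive.RAF.cytoplasm"} for MEK bound to RAF in the cytoplasm.
#' Tokens are plain strings, hence hashable and totally (lexicographically)
#' ordered; two agents with equal labels are statistically exchangeable.
#'
#' @param species species name, e.g. \code{"MEK"}.
#' @param activation \code{"active"} or \code{"inactive"}.
#' @param partner bound partner species name, or \code{"none"} for a free
#'   molecule.
#' @param compartment one of \code{"nucleus"}, \code{"cytoplasm"},
#'   \code{"membrane"}, \code{"extracellular"}.
#' @return character scalar label token.
#' @examples
#' state_label("MEK", "inactive", "RAF", "cytoplasm")
#' @export
state_label <- function(species, activation = c("inactive", "active"),
                        partner = "none",
                        compartment = c("cytoplasm", "nucleus", "membrane",
                                        "extracellular")) {
  activation <- match.arg(activation)
  compartment <- match.arg(compartment)
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  paste(species, activation, partner, compartment, sep = ".")
}

#' Parse state label tokens
#'
#' @param x character vector of label tokens produced by [state_label()].
#' @return data.frame with columns \code{species}, \code{activation},
#'   \code{partner}, \code{compartment}.
#' @export
parse_label <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed state label(s): ", paste(x[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(species = m[, 1L], activation = m[, 2L], partner = m[, 3L],
             compartment = m[, 4L])
}

# internal: compartment integer codes shared with the C++ engine
.comp_names <- c("nucleus", "cytoplasm", "membrane", "extracellular")
# species-level compartment classes (motion domains)
.comp_classes <- c("nucleus", "cytoplasm", "nucleus+cytoplasm",
                   "extracellular", "membrane")
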