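#' Tissue property table
#'
#' Electrical properties of the tissue classes used by the thigh phantom:
#' conductivity in S/m (enters the eddy-current solve) and relative
#' permittivity (carried as metadata only; displacement currents are not part
#' of the quasi-static formulation).
#'
#' @param label character vector of tissue-class names
#' @param conductivity_S_per_m numeric, electrical conductivity in S/m
#' @param relative_permittivity numeric, relative permittivity (metadata)
#' @return a `data.frame` of class `tissue_table`
#' @export
tissue_table <- function(label, conductivity_S_per_m, relative_permittivity) {
  stopifnot(length(label) == length(conductivity_S_per_m),
            length(label) == length(relative_permittivity))
  if (anyDuplicated(label)) stop("duplicate tissue labels")
  if (any(conductivity_S_per_m < 0)) stop("conductivity must be >= 0")
  tab <- data.frame(label = as.character(label),
                    conductivity_S_per_m = as.numeric(conductivity_S_per_m),
                    relative_permittivity = as.numeric(relative_permittivity),
                    stringsAsFactors = FALSE)
  class(tab) <- c("tissue_table", "data.frame")
  tab
}

#' Default tissue properties at the stimulation frequency
#'
#' Literature values in the relevant kHz range for the six tissue classes of
#' the phantom plus the non-conducting background (air). Conductivities in
#' S/m; skin is nearly insulating at these frequencies.
#'
#' @return a `tissue_table`
#' @export
default_tissue_table <- function() {
  tissue_table(
    label = c("background", "skin", "fat", "muscle", "vessel", "nerve", "bone"),
    conductivity_S_per_m = c(0, 2.0e-4, 0.024, 0.34, 0.31, 0.03, 0.082),
    relative_permittivity = c(1, 1.1e3, 2.8e3, 5.2e4, 1.7e4, 5.0e5, 8.4e2)
  )
}

#' Read / write a tissue table
#'
#' @param path CSV file with columns `label`, `conductivity_S_per_m`,
#'   `relative_permittivity`
#' @return `read_tissue_table` returns a `tissue_table`
#' @export
read_tissue_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tissue_table(tab$label, tab$conductivity_S_per_m, tab$relative_permittivity)
}

#' @rdname read_tissue_table
#' @param table a `tissue_table`
#' @export
write_tissue_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
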