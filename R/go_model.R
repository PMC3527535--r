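#' The Go contact Hamiltonian
#'
#' Native-centric energetics: the energy of a conformation is
#' `epsilon * n_formed`, where `n_formed` is the number of native contacts
#' present. Non-native contacts are sterically allowed but contribute zero.
#' With the conventional `epsilon = -1` the energy equals minus the number
#' of formed native contacts, and temperature is measured in units of
#' `|epsilon| / k_B` with `k_B = 1`.
#'
#' @param native_map the native [contact_map()].
#' @param epsilon interaction energy per native contact; must be negative.
#' @return An object of class `go_model`.
#' @export
go_model <- function(native_map, epsilon = -1) {
  if (!inherits(native_map, "contact_map")) native_map <- contact_map(native_map)
  if (nrow(native_map) == 0L) stop("native contact map is empty")
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon < 0))
    stop("`epsilon` must be a single negative number")
  structure(list(native_map = native_map, epsilon = epsilon), class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat(sprintf("<go_model> %d native contacts, epsilon = %g\n",
              nrow(x$native_map), x$epsilon))
  invisible(x)
}

#' Go energy of a conformation
#'
#' @param conf a [lattice_conformation()].
#' @param model a [go_model()].
#' @return Energy in units of `|epsilon|` (a non-positive multiple of
#'   `|epsilon|`).
#' @export
go_energy <- function(conf, model) {
  formed <- compute_contacts(conf)
  n_formed <- sum(contact_key(formed) %in% contact_key(model$native_map))
  model$epsilon * n_formed
}

#' Metropolis acceptance rule
#'
#' Accept an energy change `delta_e` at temperature `temperature` with
#' probability `min(1, exp(-delta_e / temperature))` (`k_B = 1`).
#'
#' @param delta_e proposed energy change.
#' @param temperature temperature in `|epsilon| / k_B` units; must be positive.
#' @param n number of independent draws.
#' @return Logical vector of length `n`.
#' @export
metropolis_accept <- function(delta_e, temperature, n = 1L) {
  if (!(is.numeric(temperature) && length(temperature) == 1L && temperature > 0))
    stop("`temperature` must be a single positive number")
  p <- min(1, exp(-delta_e / temperature))
  stats::runif(n) < p
}
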