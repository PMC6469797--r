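#' Define a J-coupled spin system
#'
#' A metabolite is described by one or more mutually uncoupled proton groups
#' ("subsystems"); each subsystem carries chemical shifts (ppm) and a
#' symmetric J-coupling matrix (Hz). Uncoupled groups are simulated
#' independently and their signals summed, which keeps Hilbert spaces small
#' (the largest shipped subsystem has 6 spins).
#'
#' @param name Metabolite name.
#' @param shifts Chemical shifts in ppm (one subsystem), or a list of shift
#'   vectors (several subsystems).
#' @param j J-coupling matrix in Hz matching `shifts` (or list of matrices).
#'   `NULL` means no couplings.
#' @return An object of class `"spin_system"`: a list with `name` and
#'   `subsystems`, each subsystem a list of `shifts` and `j`.
#' @export
spin_system <- function(name, shifts, j = NULL) {
  if (!is.list(shifts)) shifts <- list(shifts)
  if (!is.null(j) && !is.list(j)) j <- list(j)
  subsystems <- lapply(seq_along(shifts), function(i) {
    s <- shifts[[i]]
    n <- length(s)
    stopifnot(n >= 1, all(is.finite(s)))
    jm <- if (is.null(j) || is.null(j[[i]])) matrix(0, n, n) else j[[i]]
    stopifnot(nrow(jm) == n, ncol(jm) == n)
    if (max(abs(jm - t(jm))) > 1e-9) stop("J matrix must be symmetric")
    diag(jm) <- 0
    list(shifts = s, j = jm)
  })
  structure(list(name = name, subsystems = subsystems),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  ns <- vapply(x$subsystems, function(s) length(s$shifts), integer(1))
  cat(sprintf("Spin system '%s': %d proton(s) in %d uncoupled group(s)\n",
              x$name, sum(ns), length(ns)))
  invisible(x)
}

n_protons <- function(system) {
  sum(vapply(system$subsystems, function(s) length(s$shifts), integer(1)))
}

# symmetric J matrix from an edge list (i, j, value)
j_mat <- function(n, ...) {
  m <- matrix(0, n, n)
  for (e in list(...)) {
    m[e[1], e[2]] <- e[3]
    m[e[2], e[1]] <- e[3]
  }
  m
}

#' Library of brain-metabolite spin systems
#'
#' Proton chemical shifts and scalar couplings for the ten metabolites used in
#' the linear-combination basis: NAA, NAAG, total creatine (tCr), total
#' choline (tCho), aspartate (Asp), glutamate (Glu), glutamine (Gln),
#' glutathione (GSH), GABA and myo-inositol (mI). Values follow the standard
#' published tabulations of brain metabolite shifts/couplings. Some systems
#' are reduced to their dominant observed proton groups to keep the simulation
#' compact: NAAG is represented by its acetyl singlet and aspartyl group, GSH
#' by its cysteinyl group plus the glycine singlet, and choline methylene
#' protons are carried as uncoupled two-proton lines.
#'
#' @param names Optional subset of metabolite names.
#' @return Named list of [spin_system()] objects.
#' @export
spin_system_library <- function(names = NULL) {
  lib <- list(
    NAA = spin_system("NAA",
      shifts = list(c(2.008, 2.008, 2.008),              # acetyl CH3
                    c(4.382, 2.673, 2.486)),             # aspartyl CH-CH2
      j = list(NULL,
               j_mat(3, c(1, 2, 3.86), c(1, 3, 9.82), c(2, 3, -15.59)))),
    NAAG = spin_system("NAAG",
      shifts = list(c(2.042, 2.042, 2.042),
                    c(4.607, 2.721, 2.519)),
      j = list(NULL,
               j_mat(3, c(1, 2, 4.41), c(1, 3, 9.52), c(2, 3, -15.91)))),
    tCr = spin_system("tCr",
      shifts = list(c(3.027, 3.027, 3.027),              # N-CH3
                    c(3.913, 3.913))),                   # CH2
    tCho = spin_system("tCho",
      shifts = list(rep(3.185, 9),                       # N(CH3)3
                    c(4.054, 4.054),                     # OCH2
                    c(3.501, 3.501))),                   # NCH2
    Asp = spin_system("Asp",
      shifts = c(3.891, 2.801, 2.653),
      j = j_mat(3, c(1, 2, 3.65), c(1, 3, 9.11), c(2, 3, -17.43))),
    Glu = spin_system("Glu",
      shifts = c(3.743, 2.038, 2.120, 2.338, 2.352),
      j = j_mat(5, c(1, 2, 7.33), c(1, 3, 4.65), c(2, 3, -14.85),
                c(2, 4, 6.41), c(2, 5, 8.41), c(3, 4, 8.48),
                c(3, 5, 6.88), c(4, 5, -15.92))),
    Gln = spin_system("Gln",
      shifts = c(3.753, 2.129, 2.109, 2.432, 2.454),
      j = j_mat(5, c(1, 2, 5.85), c(1, 3, 6.50), c(2, 3, -14.45),
                c(2, 4, 9.16), c(2, 5, 6.35), c(3, 4, 6.88),
                c(3, 5, 9.25), c(4, 5, -15.92))),
    GSH = spin_system("GSH",
      shifts = list(c(4.561, 2.926, 2.975),              # cysteinyl
                    c(3.769, 3.769)),                    # glycine CH2
      j = list(j_mat(3, c(1, 2, 7.09), c(1, 3, 4.71), c(2, 3, -14.06)),
               NULL)),
    GABA = spin_system("GABA",
      shifts = c(3.013, 3.013, 1.889, 1.889, 2.284, 2.284),
      j = j_mat(6, c(1, 3, 7.76), c(1, 4, 6.17), c(2, 3, 6.17),
                c(2, 4, 7.76), c(3, 5, 7.43), c(3, 6, 6.67),
                c(4, 5, 6.67), c(4, 6, 7.43))),
    mI = spin_system("mI",
      shifts = c(3.522, 4.054, 3.522, 3.614, 3.269, 3.614),
      j = j_mat(6, c(1, 2, 2.89), c(2, 3, 3.01), c(3, 4, 10.00),
                c(4, 5, 9.49), c(5, 6, 9.48), c(1, 6, 10.00)))
  )
  if (is.null(names)) return(lib)
  missing <- setdiff(names, names(lib))
  if (length(missing))
    stop("unknown metabolite(s): ", paste(missing, collapse = ", "))
  lib[names]
}
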