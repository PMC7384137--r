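#' Radioactive decay constant
#'
#' `lambda = ln(2) / T_half`.
#'
#' @param half_life half-life in seconds (> 0).
#' @return Decay constant in 1/s.
#' @examples
#' decay_constant(2736)  # Bi-213, 45.6 min
#' @export
decay_constant <- function(half_life) {
  if (any(!is.finite(half_life) | half_life <= 0))
    stop_config("decay_constant: half_life must be > 0")
  log(2) / half_life
}

#' Atom count from activity
#'
#' `N = A / lambda`: the number of atoms sustaining activity `A`.
#'
#' @param A activity in Bq (>= 0).
#' @param lambda decay constant in 1/s (> 0).
#' @return Number of atoms.
#' @examples
#' # 3.2 mCi of Bi-213: ~4.67e11 atoms
#' atoms_from_activity(1.184e8, decay_constant(45.6 * 60))
#' @export
atoms_from_activity <- function(A, lambda) {
  if (any(!is.finite(lambda) | lambda <= 0))
    stop_config("atoms_from_activity: lambda must be > 0")
  if (any(A < 0)) stop_config("atoms_from_activity: A must be >= 0")
  A / lambda
}

#' Activity from an atom count
#'
#' Inverse of [atoms_from_activity()]: `A = lambda N`.
#'
#' @param N number of atoms (>= 0).
#' @param lambda decay constant in 1/s.
#' @return Activity in Bq.
#' @export
activity_from_atoms <- function(N, lambda) {
  if (any(!is.finite(lambda) | lambda < 0))
    stop_config("activity_from_atoms: lambda must be >= 0")
  lambda * N
}

#' Define a nuclide
#'
#' @param name nuclide label.
#' @param half_life half-life in seconds; `Inf` marks a terminal (treated
#'   as stable) member.
#' @param modes list of decay modes, each a list with elements `fraction`
#'   (branching fraction), `mode` (`"alpha"` or `"beta"`), `energy_MeV`
#'   (alpha energy, `NA` for beta), and `daughter` (daughter name or `NA`
#'   for a terminal branch).
#' @return An object of class `nuclide`.
#' @export
nuclide <- function(name, half_life, modes = list()) {
  if (!is.finite(half_life) && length(modes) > 0L)
    stop_config("nuclide: a terminal nuclide cannot have decay modes")
  if (is.finite(half_life) && half_life <= 0)
    stop_config("nuclide: half_life must be > 0")
  if (length(modes) > 0L) {
    fr <- vapply(modes, `[[`, numeric(1), "fraction")
    if (abs(sum(fr) - 1) > 1e-6)
      stop_config("nuclide %s: branching fractions sum to %.8f, not 1",
                  name, sum(fr))
    for (m in modes) {
      if (identical(m$mode, "alpha") &&
          (!is.finite(m$energy_MeV) || m$energy_MeV <= 0))
        stop_config("nuclide %s: alpha mode needs a positive energy", name)
    }
  }
  structure(list(name = name, half_life = half_life, modes = modes),
            class = "nuclide")
}

#' Assemble a decay chain
#'
#' Nuclides must be given parent-first; every non-terminal daughter must be
#' present and the graph must be acyclic.
#'
#' @param nuclides list of [nuclide()] objects.
#' @return An object of class `decay_chain`.
#' @export
decay_chain <- function(nuclides) {
  names(nuclides) <- vapply(nuclides, `[[`, character(1), "name")
  for (k in seq_along(nuclides)) {
    for (m in nuclides[[k]]$modes) {
      if (is.na(m$daughter)) next
      pos <- match(m$daughter, names(nuclides))
      if (is.na(pos))
        stop_config("decay_chain: daughter %s of %s missing from the chain",
                    m$daughter, nuclides[[k]]$name)
      if (pos <= k)
        stop_config("decay_chain: cycle or misordering at %s -> %s",
                    nuclides[[k]]$name, m$daughter)
    }
  }
  structure(list(nuclides = nuclides), class = "decay_chain")
}

#' Built-in decay chains for the Bi-213 payload
#'
#' Two chains are provided:
#' \describe{
#'   \item{`"bi213_simple"`}{the integration-test simplification: every
#'     Bi-213 decay is counted as one 8.3 MeV alpha emission
#'     (alpha yield 1 per decay).}
#'   \item{`"bi213_full"`}{the approximate branched chain:
#'     Bi-213 (45.6 min) decays 97.9% by beta to Po-213 (3.7 us), which
#'     emits an 8.375 MeV alpha to Pb-209; the remaining 2.1% is a
#'     5.87 MeV alpha to Tl-209 (2.16 min), which betas to Pb-209.
#'     Pb-209 is treated as terminal on the 0.1 s simulation scale.}
#' }
#'
#' @param name chain identifier.
#' @return A [decay_chain()].
#' @export
builtin_decay_chain <- function(name = c("bi213_simple", "bi213_full")) {
  name <- match.arg(name)
  t_bi213 <- 45.6 * 60  # 2736 s; the value consistent with N = A/lambda
  switch(name,
    bi213_simple = decay_chain(list(
      nuclide("Bi213", t_bi213, list(
        list(fraction = 1, mode = "alpha", energy_MeV = 8.3, daughter = "Pb209")
      )),
      nuclide("Pb209", Inf)
    )),
    bi213_full = decay_chain(list(
      nuclide("Bi213", t_bi213, list(
        list(fraction = 0.979, mode = "beta", energy_MeV = NA_real_,
             daughter = "Po213"),
        list(fraction = 0.021, mode = "alpha", energy_MeV = 5.87,
             daughter = "Tl209")
      )),
      nuclide("Po213", 3.72e-6, list(
        list(fraction = 1, mode = "alpha", energy_MeV = 8.375,
             daughter = "Pb209")
      )),
      nuclide("Tl209", 2.162 * 60, list(
        list(fraction = 1, mode = "beta", energy_MeV = NA_real_,
             daughter = "Pb209")
      )),
      nuclide("Pb209", Inf)
    ))
  )
}

# Alpha emission lines of a chain: one row per (nuclide, alpha mode).
alpha_lines <- function(chain) {
  out <- do.call(rbind, lapply(chain$nuclides, function(nc) {
    rows <- lapply(nc$modes, function(m) {
      if (!identical(m$mode, "alpha")) return(NULL)
      data.frame(nuclide = nc$name, fraction = m$fraction,
                 energy_MeV = m$energy_MeV)
    })
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out
}

#' Evolve decay-chain populations (Bateman solution)
#'
#' Closed-form solution of the branched linear decay system
#' `dN_i/dt = -lambda_i N_i + sum_p f_{p->i} lambda_p N_p`,
#' obtained from the exponential-sum recursion over the (topologically
#' ordered) chain. Total atoms, counting terminal daughters, are conserved.
#'
#' @param chain a [decay_chain()].
#' @param N0 initial atom counts, one per chain member (recycled names not
#'   required; order follows the chain).
#' @param t time or vector of times (s, >= 0).
#' @return A matrix with one row per time and one column per nuclide.
#' @export
evolve_chain <- function(chain, N0, t) {
  stopifnot(inherits(chain, "decay_chain"))
  nucs <- chain$nuclides
  m <- length(nucs)
  N0 <- rep_len(as.numeric(N0), m)
  if (any(t < 0)) stop_config("evolve_chain: t must be >= 0")
  lam <- vapply(nucs, function(nc)
    if (is.finite(nc$half_life)) decay_constant(nc$half_life) else 0, numeric(1))
  # coefficient matrix C: N_i(t) = sum_k C[i, k] exp(-lam[k] t)
  C <- matrix(0, m, m)
  for (i in seq_len(m)) {
    # feed terms from every parent p with a branch into i
    feed <- numeric(m)  # coefficients of exp(-lam[k] t) feeding nuclide i
    for (p in seq_len(i - 1L)) {
      for (md in nucs[[p]]$modes) {
        if (is.na(md$daughter) || md$daughter != nucs[[i]]$name) next
        feed <- feed + md$fraction * lam[p] * C[p, ]
      }
    }
    for (k in seq_len(m)) {
      if (k == i) next
      dl <- lam[i] - lam[k]
      if (feed[k] != 0 && abs(dl) < 1e-12 * max(lam[i], lam[k]))
        stop_config("evolve_chain: degenerate decay constants at %s",
                    nucs[[i]]$name)
      C[i, k] <- if (feed[k] != 0) feed[k] / dl else 0
    }
    C[i, i] <- N0[i] - sum(C[i, -i])
  }
  E <- exp(-outer(t, lam))  # times x modes
  out <- E %*% t(C)
  colnames(out) <- names(nucs)
  out
}

#' Cumulated activity over a time window
#'
#' Time integral of an exponentially decaying activity,
#' `(A0/lambda)(exp(-lambda t0) - exp(-lambda t1))`, equal to the expected
#' number of decays in `[t0, t1]`.
#'
#' @param A0 activity at time 0 (Bq).
#' @param lambda decay constant (1/s).
#' @param t0,t1 window bounds in seconds, `0 <= t0 <= t1` (`t1 = Inf`
#'   gives the total number of atoms `A0/lambda`).
#' @return Cumulated activity in Bq.s.
#' @examples
#' lam <- decay_constant(45.6 * 60)
#' cumulated_activity(1.79e2, lam, 0, 0.1)  # ~17.9 Bq.s
#' @export
cumulated_activity <- function(A0, lambda, t0, t1) {
  if (any(t0 < 0) || any(t1 < t0))
    stop_config("cumulated_activity: need 0 <= t0 <= t1")
  (A0 / lambda) * (exp(-lambda * t0) - exp(-lambda * t1))
}
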