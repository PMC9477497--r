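#' Elemental mass-balance audit of a trajectory
#'
#' Independent verification that the integrated flux bookkeeping conserves
#' carbon and nitrogen. Two checks are performed at every record time:
#'
#' 1. *Integrated closure*: the change in stored element (structures,
#'    reserves, products) plus the cumulative exported element (CO2, litter,
#'    excreted N) must equal the cumulative assimilated element.
#' 2. *Instantaneous ledger closure*: the signed sum of every carbon (and
#'    nitrogen) entry of the flux ledger must vanish ([ledger_closure()]).
#'
#' @param traj A `deb_trajectory` from [simulate_plant()].
#' @return List of class `mass_balance_audit` with `max_rel_C`, `max_rel_N`
#'   (worst-case relative closure errors of the integrated check),
#'   `max_ledger_C`, `max_ledger_N` (worst instantaneous imbalance,
#'   relative to the flux scale) and a per-record `table`.
#' @export
mass_balance_audit <- function(traj) {
  stopifnot(identical(traj$model, "root_shoot"))
  p <- traj$params
  s <- traj$states
  stored_C <- s[, "M_V_S"] + s[, "M_V_R"] + s[, "M_P"] +
    s[, "m_EC_S"] * s[, "M_V_S"] + s[, "m_EN_S"] * s[, "M_V_S"] +
    s[, "m_EC_R"] * s[, "M_V_R"] + s[, "m_EN_R"] * s[, "M_V_R"]
  stored_N <- p$n_NV * (s[, "M_V_S"] + s[, "M_V_R"] + s[, "M_P"]) +
    p$n_NE * (s[, "m_EN_S"] * s[, "M_V_S"] + s[, "m_EN_R"] * s[, "M_V_R"])
  cum0 <- function(col) s[, col] - s[1L, col]
  err_C <- (stored_C - stored_C[1L]) + cum0("M_CO2") + cum0("M_litter_C") -
    cum0("M_A_C")
  err_N <- (stored_N - stored_N[1L]) + cum0("M_litter_N") + cum0("N_excess") -
    cum0("M_A_N")
  scale_C <- pmax(stored_C[1L] + cum0("M_A_C"), .Machine$double.eps)
  scale_N <- pmax(stored_N[1L] + cum0("M_A_N"), .Machine$double.eps)
  led <- apply(traj$ledgers, 1L, function(l) {
    b <- ledger_closure(l, p)
    s <- max(1, abs(l[["J_A_C"]]), abs(l[["J_EC_cat_S"]]),
             abs(l[["J_EC_cat_R"]]))
    c(b$C_balance / s, b$N_balance / s)
  })
  res <- list(max_rel_C = max(abs(err_C) / scale_C),
              max_rel_N = max(abs(err_N) / scale_N),
              max_ledger_C = max(abs(led[1L, ])),
              max_ledger_N = max(abs(led[2L, ])),
              table = data.frame(t = traj$times,
                                 rel_err_C = err_C / scale_C,
                                 rel_err_N = err_N / scale_N,
                                 ledger_C = led[1L, ],
                                 ledger_N = led[2L, ]))
  class(res) <- "mass_balance_audit"
  res
}

#' @export
print.mass_balance_audit <- function(x, ...) {
  cat(sprintf(paste0("<mass_balance_audit> integrated closure: ",
                     "C %.3g, N %.3g (relative); ",
                     "ledger closure: C %.3g, N %.3g (relative)\n"),
              x$max_rel_C, x$max_rel_N, x$max_ledger_C, x$max_ledger_N))
  invisible(x)
}
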