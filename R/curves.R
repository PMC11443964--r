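#' Parametric gating-curve forms
#'
#' Model-definition files describe every steady-state activation and time
#' constant with one of a small set of closed parametric forms. The same
#' encoding is interpreted by the compiled right-hand side during numerical
#' integration, so the YAML file is the single source of truth for kinetics.
#'
#' Forms (`p` is the parameter vector):
#' * `const`:     p1
#' * `boltz`:     1 / (1 + exp((V + p1)/p2))
#' * `sigtau`:    p1 + p2 / (1 + exp((V + p3)/p4))
#' * `dblexptau`: p1 + p2 / (exp((V + p3)/p4) + exp((V + p5)/p6))
#' * `prodtau`:   (p1/(1 + exp((V + p2)/p3))) * (p4 + p5/(1 + exp((V + p6)/p7)))
#' @name curve-forms
#' @keywords internal
NULL

.curve_forms <- c(const = 0L, boltz = 1L, sigtau = 2L, dblexptau = 3L,
                  prodtau = 4L)

curve_form_id <- function(curve) {
  id <- .curve_forms[curve$form]
  if (is.na(id)) stop("unknown curve form: ", curve$form)
  id
}

#' Evaluate a parametric gating curve
#' @param curve list with elements `form` (character) and `p` (numeric)
#' @param V membrane potential (mV), vectorized
#' @return numeric vector of curve values
#' @keywords internal
eval_curve <- function(curve, V) {
  p <- curve$p
  switch(curve$form,
    const = rep_len(p[1], length(V)),
    boltz = 1 / (1 + exp((V + p[1]) / p[2])),
    sigtau = p[1] + p[2] / (1 + exp((V + p[3]) / p[4])),
    dblexptau = p[1] + p[2] / (exp((V + p[3]) / p[4]) + exp((V + p[5]) / p[6])),
    prodtau = (p[1] / (1 + exp((V + p[2]) / p[3]))) *
      (p[4] + p[5] / (1 + exp((V + p[6]) / p[7]))),
    stop("unknown curve form: ", curve$form)
  )
}

#' Analytic dV-derivative of a parametric gating curve
#' @inheritParams eval_curve
#' @keywords internal
eval_curve_dV <- function(curve, V) {
  p <- curve$p
  switch(curve$form,
    const = rep_len(0, length(V)),
    boltz = {
      f <- 1 / (1 + exp((V + p[1]) / p[2]))
      -f * (1 - f) / p[2]
    },
    sigtau = {
      f <- 1 / (1 + exp((V + p[3]) / p[4]))
      -p[2] * f * (1 - f) / p[4]
    },
    dblexptau = {
      den <- exp((V + p[3]) / p[4]) + exp((V + p[5]) / p[6])
      dden <- exp((V + p[3]) / p[4]) / p[4] + exp((V + p[5]) / p[6]) / p[6]
      -p[2] * dden / den^2
    },
    prodtau = {
      f1 <- 1 / (1 + exp((V + p[2]) / p[3]))
      f2 <- 1 / (1 + exp((V + p[6]) / p[7]))
      a <- p[1] * f1
      b <- p[4] + p[5] * f2
      da <- -p[1] * f1 * (1 - f1) / p[3]
      db <- -p[5] * f2 * (1 - f2) / p[7]
      da * b + a * db
    },
    stop("unknown curve form: ", curve$form)
  )
}
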