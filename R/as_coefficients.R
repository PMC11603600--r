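# Coefficients of the fifth-order correction polynomials P1 and P2 used by
# q_ayala_schlegel(): entry (i, j) multiplies x^(i-1) * y^(j-1); only terms
# with (i-1) + (j-1) <= 5 are populated and the constant term is zero, so
# the correction tends to 1 as x, y -> 0.
#
# Calibrated against the exact torsional eigensolver (torsion_oracle) on
# x in [0.04, 0.6], y in [0, 12], M = sigma in {2, 3}; regenerate with
# tools/fit-as-coefficients.R.

.as_P1 <- matrix(c(
  c(0.000000000000000e+00, -5.684749495603794e+00, 4.821656690428301e-01, -4.163086422180104e-01, 1.430152045283905e-01, -7.690549814215940e-03),
  c(-3.303943752965295e+01, 6.789015801123248e+00, -1.115350748197630e+00, -2.592525539450907e-01, 1.357248717466803e-03, 0.000000000000000e+00),
  c(4.825028520325596e+01, -3.082488620392235e+01, -2.438955597211184e-01, 4.577859977052526e-02, 0.000000000000000e+00, 0.000000000000000e+00),
  c(-1.074919789797831e+02, 3.324229891162346e+01, 1.015311100348323e-01, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00),
  c(8.845765982887870e+01, -1.286323866156658e+01, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00),
  c(-2.941839158508011e+01, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00)
), nrow = 6, byrow = TRUE)

.as_P2 <- matrix(c(
  c(0.000000000000000e+00, -5.685948591992651e+00, 4.831040599913267e-01, -4.164682973700787e-01, 1.430159442084128e-01, -7.689876424443880e-03),
  c(-3.303978222905032e+01, 6.832281827546394e+00, -1.149306342198673e+00, -2.524510920503448e-01, 9.947131064696945e-04, 0.000000000000000e+00),
  c(4.825559531838824e+01, -3.123084617129868e+01, -5.006227727388194e-01, 1.259750771494473e-01, 0.000000000000000e+00, 0.000000000000000e+00),
  c(-1.075173029672932e+02, 3.187763239458174e+01, -3.100946456362649e-02, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00),
  c(8.850791745122648e+01, -1.532314422946635e+01, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00),
  c(-2.945303224102186e+01, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00, 0.000000000000000e+00)
), nrow = 6, byrow = TRUE)

.as_domain <- list(x = c(0, 0.6), y = c(0, 12))
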