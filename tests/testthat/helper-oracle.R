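# Frozen reference values computed with an independent high-precision
# adaptive quadrature (relative tolerance 1e-12 to 1e-13) before the
# package numerics were built. All are for sigma = 1.
oracle <- list(
  # G(y) = int_y^1 exp(beta^2 ((1/z)-1)^2)/z dz at beta = 0.1
  G_y05_b01 = 0.6950841558291243,
  G_y02_b01 = 1.6680365145508251,
  # XET coefficient at alpha = 10, beta = 0.1, g_xet = 10, g_xeh = 0
  A_a10_xet10 = 0.47475957240345906,
  # no-enzyme steady stress resultant, beta = 0.1, Gamma = 0
  S_a01_b01 = 0.009081552538079197,
  S_a1_b01 = 0.4040314829431923,
  S_a10_b01 = 1.669123512918357,
  S_a100_b01 = 2.2438821321949156,
  S_a1e4_b01 = 2.58518114296492,
  # enzyme variants at alpha = 10, beta = 0.1
  S_a10_xeh10 = 0.395741910473837,
  S_a10_xet10 = 0.753449067667393,
  # beta = 0.01
  S_a2_b001 = 1.14229809464162,
  # transient stress at t = 0.2, alpha = 5, beta = 0.1, Gamma = 0
  Strans_t02_a5 = 0.8406027366335954,
  # central finite difference (h = 0.01) of the reference stress curve
  phi_fd_a10_b01 = 23.935680051681352,
  # survivor fraction exp(-G(0.2)) at beta = 0.1 (alpha = 1)
  n_y02_a1 = 0.188617049122706,
  # 20-point log-spaced reference curve, alpha in [0.1, 100], beta = 0.1
  curve_alpha = c(0.1, 0.143844988828766, 0.206913808111479,
                  0.297635144163132, 0.428133239871939, 0.615848211066026,
                  0.885866790410083, 1.27427498570313, 1.83298071083244,
                  2.63665089873036, 3.79269019073225, 5.45559478116852,
                  7.84759970351461, 11.2883789168469, 16.2377673918872,
                  23.3572146909012, 33.5981828628378, 48.3293023857175,
                  69.5192796177561, 100),
  curve_sigma = c(0.0090815525380792, 0.0180457054790058,
                  0.0352620290966523, 0.0672263746613058, 0.12349431242341,
                  0.21502442514901, 0.349503734629951, 0.526085569432467,
                  0.73401307725549, 0.956433218168912, 1.17629664358556,
                  1.38067461623551, 1.56219699653405, 1.71836036511085,
                  1.84998083538869, 1.95968028715084, 2.05077267949415,
                  2.1265846585162, 2.19011054661732, 2.24388213219492)
)

p_base <- function(...) wall_params(beta = 0.1, ...)
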