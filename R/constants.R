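# Physical constants (SI). gamma is the proton gyromagnetic ratio over 2*pi.
MU0 <- 4e-7 * pi                 # vacuum permeability, T m / A
GAMMA_HZ_PER_T <- 42.5774785e6   # proton gamma / 2 pi, Hz / T
K_BOLTZMANN <- 1.380649e-23      # J / K
T_ROOM <- 290                    # K, reference temperature for noise figures

#' @importFrom rlang abort warn .data
#' @importFrom dplyr mutate filter arrange select bind_rows bind_cols group_by
#'   summarise ungroup across n row_number left_join
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats fft uniroot runif rnorm setNames approx
#' @importFrom utils head tail read.csv write.csv modifyList
NULL
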