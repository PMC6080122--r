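#' @importFrom data.table :=
#' @importFrom stats approx rnorm runif
#' @importFrom utils head read.csv
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c(".hour", ".N", ".SD", "rate", "ref_value",
                         "ref_time", "pad_mean", "pad_sd", "pad_n",
                         "pard_mean", "pard_sd", "pard_n"))
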