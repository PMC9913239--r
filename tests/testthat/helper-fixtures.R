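# Shared fixtures: published kinetic truths and the study design grid.

kpc_truth <- function() {
  list(arrhenius = arrhenius_params(137.63, 383112),
       delay = delay_params(800, 254920))
}

all_truths <- function() {
  list(
    STO = list(arrhenius = arrhenius_params(164.79, 455630),
               delay = delay_params(400, 127460)),
    KPC = kpc_truth(),
    Pan02 = list(arrhenius = arrhenius_params(153.63, 427712),
                 delay = delay_params(400, 127460))
  )
}

study_setpoints <- function() celsius_to_kelvin(c(42.5, 44, 46, 50))
study_durations <- function() 60 * c(3, 5, 10, 15, 20, 30, 45, 60)

# direct Arrhenius evaluation, independent of rate_constant()
k_direct <- function(lnA, ea, temp, gas = 8.314) exp(lnA - ea / (gas * temp))
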