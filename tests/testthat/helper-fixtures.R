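# Shared fixtures: the field-test Gaussian class model and small simulated
# populations, built in code at test time.

field_class_model <- function() {
  class_model(
    ocr_mean = c(haploid = 3.6, diploid = 5.5),
    ocr_sd = c(haploid = 0.47, diploid = 0.52),
    weight_mean = c(haploid = 0.40, diploid = 0.43),
    weight_sd = c(haploid = 0.049, diploid = 0.035))
}

# labelled OCR/weight records drawn directly from a class model (no
# instrument simulation), exactly n_h + n_d kernels
draw_records <- function(n_h, n_d, model = field_class_model(), seed = 1) {
  set.seed(seed)
  data.frame(
    kernel_id = sprintf("K%05d", seq_len(n_h + n_d)),
    true_class = c(rep("haploid", n_h), rep("diploid", n_d)),
    mass_g = c(rnorm(n_h, model$weight_mean[["haploid"]], model$weight_sd[["haploid"]]),
               rnorm(n_d, model$weight_mean[["diploid"]], model$weight_sd[["diploid"]])),
    ocr_pct = c(rnorm(n_h, model$ocr_mean[["haploid"]], model$ocr_sd[["haploid"]]),
                rnorm(n_d, model$ocr_mean[["diploid"]], model$ocr_sd[["diploid"]])),
    stringsAsFactors = FALSE)
}

noiseless_train <- function(so = 2, sw = 1, relax = relaxation_params(),
                            echo_times = default_echo_times()) {
  simulate_echo_train(kernel_composition(so, sw), relax,
                      acquisition_config(echo_times = echo_times))
}

# Table 2 of the field study: selection counts per cross and the printed
# accuracies (total row printed at integer precision)
table2_counts <- function() {
  data.frame(
    cross = c("ZD958", "XY335", "Zhongnongda622", "B73/Zheng58",
              "Xu178/Dan3130", "Chang7-2/Ji853"),
    identified = c(321, 315, 266, 303, 287, 310),
    true_haploids = c(308, 299, 237, 279, 274, 290),
    printed_accuracy = c(95.95, 94.94, 89.10, 92.08, 95.47, 93.55))
}
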