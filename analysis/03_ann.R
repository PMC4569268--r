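#!/usr/bin/env Rscript
# Step 3: train 5-15-1 feed-forward networks on the 30 modelling runs
# (24 train + 6 test) with Levenberg-Marquardt, early-stopping on the six
# held-out validation runs, across ten random restarts; keep the restart
# with the best validation correlation.

library(codopt)
dir.create("results", showWarnings = FALSE)

design <- cod_design()
cfg <- nn_config(algorithm = "lm", fit_split = c("train", "test"),
                 monitor_split = "validation", max_epochs = 300)
fit <- nn_restarts(design, n_hidden = 15, seeds = 1:10, config = cfg,
                   init_scale = 1)

cat("Per-restart correlations (selected by validation):\n")
print(round(fit$summary, 4))
cat(sprintf("Selected restart %d: r(train) = %.4f, r(test) = %.4f, r(validation) = %.4f\n",
            fit$best_seed, fit$report$r_train, fit$report$r_test,
            fit$report$r_validation))

nn_to_json(fit$model, "results/ann_model.json")
utils::write.csv(fit$summary, "results/ann_restarts.csv", row.names = FALSE)
utils::write.csv(fit$report$trace, "results/ann_training_trace.csv",
                 row.names = FALSE)

pred <- nn_predict(fit$model, design)
m <- model_metrics(design$observed, pred)
cat(sprintf("Selected network over all 36 runs: RMSE %.4f, MAPE %.2f%%, R^2 %.4f\n",
            m$rmse, m$mape_percent, m$r_squared))
utils::write.csv(data.frame(run = design$run, observed = design$observed,
                            predicted = pred, split = design$split),
                 "results/ann_predictions.csv", row.names = FALSE)
cat("Wrote results/ann_model.json, ann_restarts.csv, ann_training_trace.csv,",
    "ann_predictions.csv\n")
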