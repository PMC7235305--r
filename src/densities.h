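#ifndef BPSY_DENSITIES_H
#define BPSY_DENSITIES_H

double st_lpdf(double y, double nu, double mu, double sigma);
double exg_lpdf(double t, double mu, double sigma, double lambda);
double vm_lpdf(double theta, double mu, double kappa);
double tnorm_lpdf(double x, double m, double s, double lo, double hi);
double rbeta_lpdf(double x, double p, double tau);

#endif
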