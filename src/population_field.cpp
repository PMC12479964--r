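#include <Rcpp.h>
using namespace Rcpp;

// Stacked population + per-strain intracellular field, mirroring the R
// reference implementation in R/cell_model.R (cell_field) plus the
// population coupling in R/population.R. State layout (0-based):
//   y[0]                     external substrate s_X
//   y[1 + s]                 strain cell counts N_s,          s = 0..n-1
//   y[1 + n + j*n + s]       cells(strain s, species j),      j = 0..m-1
//   y[1 + n + n*m]           shared autoinducer H (quorum topologies only)
// Host species occupy fixed columns 0..13; circuit gene g has columns
// 14+3g (mRNA), 15+3g (complex), 16+3g (protein); the sRNA, if present, is
// the last column.

static const int S_SI = 0, S_A = 1, S_R = 2,
                 S_MR = 3, S_CR = 4,
                 S_MT = 5, S_CT = 6, S_PT = 7,
                 S_MM = 8, S_CM = 9, S_PM = 10,
                 S_MQ = 11, S_CQ = 12, S_PQ = 13;

// [[Rcpp::export(name = ".population_field_cpp")]]
NumericVector population_field_cpp(NumericVector y,
                                   int n_strain, int n_sp,
                                   NumericVector hp,
                                   NumericMatrix gene_kin,
                                   NumericVector prom_omega,
                                   NumericMatrix omega_scale,
                                   NumericMatrix rules,
                                   double hill_h,
                                   int srna_col, int srna_prom,
                                   double srna_dr, double k_seq,
                                   IntegerVector srna_targets,
                                   int qs, int qs_p_col, double k_syn, double d_H,
                                   NumericMatrix Mt,
                                   NumericVector outrate) {
  const double v_t = hp[0], K_t = hp[1], v_m = hp[2], K_m = hp[3],
               n_s = hp[4], w_r = hp[5], w_t = hp[6], w_m = hp[7],
               w_q = hp[8], theta_r = hp[9], theta_nr = hp[10],
               K_q = hp[11], h_q = hp[12], k_b = hp[13], k_u = hp[14],
               d_m = hp[15], gamma_max = hp[16], K_gamma = hp[17],
               n_r = hp[18], n_t = hp[19], n_m = hp[20], n_q = hp[21],
               M_mass = hp[22];
  const bool tx_cost_on = hp[23] > 0.5;
  const double xi_nt = hp[24];

  const int n = n_strain, m = n_sp;
  const int n_gene = gene_kin.nrow();
  const int n_prom = prom_omega.size();
  const int off = 1 + n;
  const int len = 1 + n + n * m + (qs ? 1 : 0);
  NumericVector dy(len);

  const double sX = y[0];
  const double sxp = sX > 0 ? sX : 0;
  const double H = qs ? (y[len - 1] > 0 ? y[len - 1] : 0) : 0;

  // population output P = sum_i max(N_i,0) * max(p_A_i, 0); gene 0 is A
  const int ipA = 14 + 2;
  double P = 0;
  for (int s = 0; s < n; ++s) {
    double Np = y[1 + s] > 0 ? y[1 + s] : 0;
    double pA = y[off + ipA * n + s];
    P += Np * (pA > 0 ? pA : 0);
  }

  double dsX = 0, dH_acc = 0;

  for (int s = 0; s < n; ++s) {
    const double *cell = &y[off];
#define SP(j) cell[(j) * n + s]
    double a = SP(S_A);
    double ap = a > 0 ? a : 0;
    double sip = SP(S_SI) > 0 ? SP(S_SI) : 0;
    double R = SP(S_R);

    double gam = gamma_max * ap / (K_gamma + ap);
    double ctot = SP(S_CR) + SP(S_CT) + SP(S_CM) + SP(S_CQ);
    for (int g = 0; g < n_gene; ++g) ctot += SP(14 + 3 * g + 1);
    double lambda = gam * ctot / M_mass;

    double import = SP(S_PT) * v_t * sxp / (K_t + sxp);
    double vcat = SP(S_PM) * v_m * sip / (K_m + sip);

    double sat_r = ap / (theta_r + ap);
    double sat_nr = ap / (theta_nr + ap);
    double tx_r = w_r * sat_r;
    double tx_t = w_t * sat_nr;
    double tx_m = w_m * sat_nr;
    double pq = SP(S_PQ) > 0 ? SP(S_PQ) : 0;
    double tx_q = w_q * sat_nr / (1.0 + std::pow(pq / K_q, h_q));

    // controller regulatory factors per promoter
    std::vector<double> fac(n_prom, 1.0);
    for (int r = 0; r < rules.nrow(); ++r) {
      int prom = (int)rules(r, 0);
      int op = (int)rules(r, 1);       // 0 repress, 1 activate
      int input = (int)rules(r, 2);    // 0 species, 1 lambda, 2 P, 3 H
      double x;
      if (input == 0) {
        x = SP((int)rules(r, 3));
      } else if (input == 1) {
        x = lambda;
      } else if (input == 2) {
        x = P;
      } else {
        x = H;
      }
      if (x < 0) x = 0;
      double ratio = std::pow(x / rules(r, 4), hill_h);
      double act = ratio / (1.0 + ratio);
      fac[prom] *= (op == 0) ? (1.0 - act) : act;
    }

    double bind_sum = 0, unbind_sum = 0, nu_sum = 0, nu_r = 0, tx_cost = 0;
#define DSP(j) dy[off + (j) * n + s]

    // one expressed unit: transcription tx, mRNA/complex indices im/ic;
    // returns nu (translation completions per min)
    auto gene_block = [&](int im, int ic, double tx, double kb_, double ku_,
                          double n_aa, double dm_) -> double {
      double mv = SP(im), cv = SP(ic);
      double bind = kb_ * R * mv;
      double unbind = ku_ * cv;
      double nu = gam * cv / n_aa;
      DSP(im) += tx - bind + unbind + nu - dm_ * mv - lambda * mv;
      DSP(ic) += bind - unbind - nu - lambda * cv;
      bind_sum += bind;
      unbind_sum += unbind;
      nu_sum += nu;
      return nu;
    };

    nu_r = gene_block(S_MR, S_CR, tx_r, k_b, k_u, n_r, d_m);
    double nu_t = gene_block(S_MT, S_CT, tx_t, k_b, k_u, n_t, d_m);
    double nu_m = gene_block(S_MM, S_CM, tx_m, k_b, k_u, n_m, d_m);
    double nu_q = gene_block(S_MQ, S_CQ, tx_q, k_b, k_u, n_q, d_m);
    DSP(S_PT) = nu_t - lambda * SP(S_PT);
    DSP(S_PM) = nu_m - lambda * SP(S_PM);
    DSP(S_PQ) = nu_q - lambda * SP(S_PQ);

    if (tx_cost_on) {
      tx_cost = xi_nt * (3 * n_r * tx_r + 3 * n_t * tx_t +
                         3 * n_m * tx_m + 3 * n_q * tx_q);
    }

    for (int g = 0; g < n_gene; ++g) {
      int im = 14 + 3 * g, ic = im + 1, ip = im + 2;
      int prom = (int)gene_kin(g, 4);
      double tx_g = prom_omega[prom] * omega_scale(s, prom) * fac[prom] * sat_nr;
      double nu_g = gene_block(im, ic, tx_g, gene_kin(g, 0), gene_kin(g, 1),
                               gene_kin(g, 2), gene_kin(g, 3));
      DSP(ip) = nu_g - lambda * SP(ip);
      if (tx_cost_on) tx_cost += xi_nt * gene_kin(g, 5) * tx_g;
    }

    if (srna_col >= 0) {
      double rv = SP(srna_col);
      double tx_c = prom_omega[srna_prom] * omega_scale(s, srna_prom) *
                    fac[srna_prom] * sat_nr;
      double dr = tx_c - srna_dr * rv - lambda * rv;
      for (int ti = 0; ti < srna_targets.size(); ++ti) {
        int mi = srna_targets[ti];
        double seq = k_seq * SP(mi) * rv;
        DSP(mi) -= seq;
        dr -= seq;
      }
      DSP(srna_col) = dr;
      if (tx_cost_on) tx_cost += xi_nt * 100.0 * tx_c;  // ~100 nt sRNA
    }

    DSP(S_R) = nu_r + nu_sum - bind_sum + unbind_sum - lambda * R;
    DSP(S_SI) = import - vcat - lambda * SP(S_SI);
    DSP(S_A) = n_s * vcat - gam * ctot - tx_cost - lambda * a;

    // population layer
    double N = y[1 + s];
    double Np = N > 0 ? N : 0;
    double dN = lambda * N - outrate[s] * N;
    for (int j = 0; j < n; ++j) dN += Mt(s, j) * y[1 + j];
    dy[1 + s] = dN;
    dsX -= Np * import;
    if (qs) dH_acc += Np * k_syn * (SP(qs_p_col) > 0 ? SP(qs_p_col) : 0);
#undef SP
#undef DSP
  }

  dy[0] = dsX;
  if (qs) dy[len - 1] = dH_acc - d_H * y[len - 1];
  return dy;
}
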