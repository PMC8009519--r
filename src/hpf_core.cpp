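#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Cell-centered cloud-in-cell (CIC) conventions used throughout:
// cubic mesh of m cells of edge h = L/m, cell c has center (c + 0.5) h.
// A particle at x spreads linearly over the two cells whose centers
// bracket x in each dimension; weights are products of the 1-D weights.

static inline int pmod(int i, int m) { return ((i % m) + m) % m; }

static inline double wrap(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;  // guard against round-off at the boundary
  return y;
}

struct CicStencil {
  int i0[3], i1[3];
  double f[3];  // fractional weight of the upper cell in each dimension
};

static inline CicStencil cic_stencil(double x, double y, double z,
                                     double L, int m) {
  CicStencil st;
  const double h = L / m;
  double c[3] = {x, y, z};
  for (int d = 0; d < 3; ++d) {
    double s = wrap(c[d], L) / h - 0.5;
    int i0 = (int)std::floor(s);
    st.f[d] = s - i0;
    st.i0[d] = pmod(i0, m);
    st.i1[d] = pmod(i0 + 1, m);
  }
  return st;
}

// [[Rcpp::export]]
NumericVector cic_assign_cpp(NumericMatrix pos, IntegerVector species,
                             int n_species, double L, int m) {
  const int n = pos.nrow();
  const double h = L / m;
  const double inv_v = 1.0 / (h * h * h);
  const int m3 = m * m * m;
  NumericVector phi(m3 * n_species);
  for (int p = 0; p < n; ++p) {
    CicStencil st = cic_stencil(pos(p, 0), pos(p, 1), pos(p, 2), L, m);
    const int s = species[p] - 1;
    const int base = m3 * s;
    const double wx[2] = {1.0 - st.f[0], st.f[0]};
    const double wy[2] = {1.0 - st.f[1], st.f[1]};
    const double wz[2] = {1.0 - st.f[2], st.f[2]};
    const int ix[2] = {st.i0[0], st.i1[0]};
    const int iy[2] = {st.i0[1], st.i1[1]};
    const int iz[2] = {st.i0[2], st.i1[2]};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c)
          phi[base + ix[a] + m * (iy[b] + m * iz[c])] +=
            wx[a] * wy[b] * wz[c] * inv_v;
  }
  phi.attr("dim") = IntegerVector::create(m, m, m, n_species);
  return phi;
}

// Field force on each particle: the exact negative gradient of the
// CIC-discretized interaction energy, i.e. the derivative of the CIC
// weights contracted with the per-species potential mesh V (kJ/mol).
static void field_forces_impl(const NumericMatrix& pos,
                              const IntegerVector& species,
                              const double* V, int m, double L,
                              NumericMatrix& F) {
  const int n = pos.nrow();
  const double h = L / m;
  const int m3 = m * m * m;
  for (int p = 0; p < n; ++p) {
    CicStencil st = cic_stencil(pos(p, 0), pos(p, 1), pos(p, 2), L, m);
    const int base = m3 * (species[p] - 1);
    const double wx[2] = {1.0 - st.f[0], st.f[0]};
    const double wy[2] = {1.0 - st.f[1], st.f[1]};
    const double wz[2] = {1.0 - st.f[2], st.f[2]};
    const double dw[2] = {-1.0 / h, 1.0 / h};
    const int ix[2] = {st.i0[0], st.i1[0]};
    const int iy[2] = {st.i0[1], st.i1[1]};
    const int iz[2] = {st.i0[2], st.i1[2]};
    double fx = 0, fy = 0, fz = 0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int c = 0; c < 2; ++c) {
          const double v = V[base + ix[a] + m * (iy[b] + m * iz[c])];
          fx -= dw[a] * wy[b] * wz[c] * v;
          fy -= wx[a] * dw[b] * wz[c] * v;
          fz -= wx[a] * wy[b] * dw[c] * v;
        }
    F(p, 0) = fx; F(p, 1) = fy; F(p, 2) = fz;
  }
}

// [[Rcpp::export]]
NumericMatrix cic_field_forces_cpp(NumericMatrix pos, IntegerVector species,
                                   NumericVector V, double L) {
  IntegerVector dim = V.attr("dim");
  const int m = dim[0];
  NumericMatrix F(pos.nrow(), 3);
  field_forces_impl(pos, species, V.begin(), m, L, F);
  return F;
}

// Trilinear interpolation of a 3-component mesh field (dims m,m,m,3)
// at particle positions; used for the electrostatic field E.
// [[Rcpp::export]]
NumericMatrix cic_interp_vec_cpp(NumericMatrix pos, NumericVector E,
                                 double L) {
  IntegerVector dim = E.attr("dim");
  const int m = dim[0];
  const int m3 = m * m * m;
  const int n = pos.nrow();
  NumericMatrix out(n, 3);
  for (int p = 0; p < n; ++p) {
    CicStencil st = cic_stencil(pos(p, 0), pos(p, 1), pos(p, 2), L, m);
    const double wx[2] = {1.0 - st.f[0], st.f[0]};
    const double wy[2] = {1.0 - st.f[1], st.f[1]};
    const double wz[2] = {1.0 - st.f[2], st.f[2]};
    const int ix[2] = {st.i0[0], st.i1[0]};
    const int iy[2] = {st.i0[1], st.i1[1]};
    const int iz[2] = {st.i0[2], st.i1[2]};
    for (int d = 0; d < 3; ++d) {
      double acc = 0;
      const double* Ed = E.begin() + m3 * d;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c)
            acc += wx[a] * wy[b] * wz[c] *
                   Ed[ix[a] + m * (iy[b] + m * iz[c])];
      out(p, d) = acc;
    }
  }
  return out;
}

static double bonded_impl(const NumericMatrix& pos,
                          const IntegerMatrix& bonds,
                          const NumericVector& kb, const NumericVector& r0,
                          double L, NumericMatrix& F) {
  const int nb = bonds.nrow();
  double energy = 0.0;
  for (int b = 0; b < nb; ++b) {
    const int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    double d[3];
    for (int k = 0; k < 3; ++k) {
      double dd = pos(i, k) - pos(j, k);
      dd -= L * std::round(dd / L);  // minimum image
      d[k] = dd;
    }
    const double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r > 0.5 * L)
      stop("bond %d-%d has length %.3f nm > box_edge/2: minimum image ambiguous",
           i + 1, j + 1, r);
    const double dr = r - r0[b];
    energy += 0.5 * kb[b] * dr * dr;
    if (r > 1e-12) {
      const double fmag = -kb[b] * dr / r;  // along d, acting on i
      for (int k = 0; k < 3; ++k) {
        F(i, k) += fmag * d[k];
        F(j, k) -= fmag * d[k];
      }
    }
  }
  return energy;
}

// [[Rcpp::export]]
List bonded_forces_cpp(NumericMatrix pos, IntegerMatrix bonds,
                       NumericVector kb, NumericVector r0, double L) {
  NumericMatrix F(pos.nrow(), 3);
  double e = bonded_impl(pos, bonds, kb, r0, L, F);
  return List::create(_["forces"] = F, _["energy"] = e);
}

// Minimum-image pair distance histogram.  If `same` the two selections
// are identical and each unordered pair is counted twice (once per
// center); otherwise all cross pairs are counted once.
// [[Rcpp::export]]
NumericVector pair_hist_cpp(NumericMatrix A, NumericMatrix B, bool same,
                            double L, double rmax, int nbins) {
  NumericVector counts(nbins);
  const double dr = rmax / nbins;
  const int na = A.nrow(), nb = B.nrow();
  for (int i = 0; i < na; ++i) {
    const int jstart = same ? i + 1 : 0;
    for (int j = jstart; j < nb; ++j) {
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = A(i, k) - B(j, k);
        d -= L * std::round(d / L);
        r2 += d * d;
      }
      const double r = std::sqrt(r2);
      if (r < rmax) {
        int bin = (int)(r / dr);
        if (bin >= nbins) bin = nbins - 1;
        counts[bin] += same ? 2.0 : 1.0;
      }
    }
  }
  return counts;
}

// Random sequential placement of whole molecules with a minimum
// inter-bead distance, using a cell list.  Each molecule is grown as a
// freely jointed chain with the given successive bond lengths from a
// uniformly random anchor.  Uses R's RNG for reproducibility.
// [[Rcpp::export]]
List build_positions_cpp(IntegerVector template_id, List bond_lengths,
                         double L, double min_dist, int max_trials) {
  const int nmol = template_id.size();
  std::vector<std::vector<double>> blen;
  for (int t = 0; t < bond_lengths.size(); ++t) {
    NumericVector v = bond_lengths[t];
    blen.push_back(std::vector<double>(v.begin(), v.end()));
  }
  int ntot = 0;
  for (int i = 0; i < nmol; ++i) ntot += (int)blen[template_id[i] - 1].size() + 1;

  // cell list with cell edge >= min_dist
  int mc = std::max(1, (int)std::floor(L / std::max(min_dist, 1e-6)));
  if (mc > 64) mc = 64;
  const double hc = L / mc;
  std::vector<int> head(mc * mc * mc, -1), nxt(ntot, -1);
  NumericMatrix pos(ntot, 3);
  const double md2 = min_dist * min_dist;

  auto cell_of = [&](const double* x) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int i = (int)(wrap(x[d], L) / hc);
      if (i >= mc) i = mc - 1;
      c[d] = i;
    }
    return c[0] + mc * (c[1] + mc * c[2]);
  };
  auto clash = [&](const double* x) {
    int cx = (int)(wrap(x[0], L) / hc), cy = (int)(wrap(x[1], L) / hc),
        cz = (int)(wrap(x[2], L) / hc);
    if (cx >= mc) cx = mc - 1;
    if (cy >= mc) cy = mc - 1;
    if (cz >= mc) cz = mc - 1;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          int idx = pmod(cx + a, mc) +
                    mc * (pmod(cy + b, mc) + mc * pmod(cz + c, mc));
          for (int q = head[idx]; q >= 0; q = nxt[q]) {
            double r2 = 0;
            for (int d = 0; d < 3; ++d) {
              double dd = x[d] - pos(q, d);
              dd -= L * std::round(dd / L);
              r2 += dd * dd;
            }
            if (r2 < md2) return true;
          }
        }
    return false;
  };

  int placed = 0;
  std::vector<double> cand;
  for (int mol = 0; mol < nmol; ++mol) {
    const std::vector<double>& bl = blen[template_id[mol] - 1];
    const int nb = (int)bl.size() + 1;
    cand.assign(3 * nb, 0.0);
    bool ok = false;
    for (int trial = 0; trial < max_trials && !ok; ++trial) {
      for (int d = 0; d < 3; ++d) cand[d] = unif_rand() * L;
      for (int k = 1; k < nb; ++k) {
        // random unit step of the bond length
        double u[3], norm = 0;
        do {
          norm = 0;
          for (int d = 0; d < 3; ++d) { u[d] = norm_rand(); norm += u[d] * u[d]; }
        } while (norm < 1e-12);
        norm = std::sqrt(norm);
        for (int d = 0; d < 3; ++d)
          cand[3 * k + d] = cand[3 * (k - 1) + d] + bl[k - 1] * u[d] / norm;
      }
      ok = true;
      for (int k = 0; k < nb && ok; ++k)
        if (clash(&cand[3 * k])) ok = false;
    }
    if (!ok) {
      const double vol = L * L * L;
      stop("placement failed for molecule %d of %d after %d trials "
           "(approx packing fraction %.3f)",
           mol + 1, nmol, max_trials,
           placed * (4.0 / 3.0) * M_PI * std::pow(min_dist / 2, 3) / vol);
    }
    for (int k = 0; k < nb; ++k) {
      for (int d = 0; d < 3; ++d) pos(placed, d) = wrap(cand[3 * k + d], L);
      double x[3] = {pos(placed, 0), pos(placed, 1), pos(placed, 2)};
      int idx = cell_of(x);
      nxt[placed] = head[idx];
      head[idx] = placed;
      ++placed;
    }
  }
  return List::create(_["positions"] = pos);
}

// Velocity-Verlet integration of n_steps steps against FROZEN meshes
// (per-species potential V, optional electrostatic field E), harmonic
// bonds, and an Andersen thermostat (full per-particle velocity redraw
// with probability p_coll per step).  Positions are unwrapped; CIC uses
// the periodic wrap internally.
// [[Rcpp::export]]
List integrate_segment_cpp(NumericMatrix pos_, NumericMatrix vel_,
                           NumericVector mass, NumericVector charge,
                           IntegerVector species, NumericVector V,
                           Nullable<NumericVector> E_, IntegerMatrix bonds,
                           NumericVector kb, NumericVector r0, double L,
                           int n_steps, double dt, double p_coll,
                           double kBT, bool thermostat) {
  NumericMatrix pos = clone(pos_);
  NumericMatrix vel = clone(vel_);
  const int n = pos.nrow();
  IntegerVector dim = V.attr("dim");
  const int m = dim[0];
  const bool has_e = E_.isNotNull();
  NumericVector E;
  if (has_e) E = E_.get();

  NumericMatrix F(n, 3);
  std::vector<double> sig(n);
  for (int p = 0; p < n; ++p) sig[p] = std::sqrt(kBT / mass[p]);

  double e_bond = 0.0;
  auto forces = [&]() {
    field_forces_impl(pos, species, V.begin(), m, L, F);
    if (has_e) {
      NumericMatrix Ep = cic_interp_vec_cpp(pos, E, L);
      for (int p = 0; p < n; ++p)
        if (charge[p] != 0.0)
          for (int d = 0; d < 3; ++d) F(p, d) += charge[p] * Ep(p, d);
    }
    e_bond = bonded_impl(pos, bonds, kb, r0, L, F);
  };
  forces();

  for (int step = 0; step < n_steps; ++step) {
    for (int p = 0; p < n; ++p) {
      const double a = 0.5 * dt / mass[p];
      for (int d = 0; d < 3; ++d) {
        vel(p, d) += a * F(p, d);
        pos(p, d) += dt * vel(p, d);
      }
    }
    forces();
    for (int p = 0; p < n; ++p) {
      const double a = 0.5 * dt / mass[p];
      for (int d = 0; d < 3; ++d) vel(p, d) += a * F(p, d);
    }
    if (thermostat) {
      for (int p = 0; p < n; ++p)
        if (unif_rand() < p_coll)
          for (int d = 0; d < 3; ++d) vel(p, d) = sig[p] * norm_rand();
    }
  }
  double ke = 0.0;
  for (int p = 0; p < n; ++p)
    for (int d = 0; d < 3; ++d) ke += 0.5 * mass[p] * vel(p, d) * vel(p, d);
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["kinetic_energy"] = ke, _["bonded_energy"] = e_bond);
}

// Brute-force O(N^2) inter-molecular contact edges: molecules i,j are
// connected iff any inter-molecular bead pair lies within cutoff under
// minimum image.  Returns a 2-column matrix of 1-based molecule-index
// pairs (indices into the sorted unique molecule ids, done in R).
// [[Rcpp::export]]
IntegerMatrix contact_edges_cpp(NumericMatrix pos, IntegerVector mol,
                                double L, double cutoff) {
  const int n = pos.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> ei, ej;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      double r2 = 0;
      for (int k = 0; k < 3; ++k) {
        double d = pos(i, k) - pos(j, k);
        d -= L * std::round(d / L);
        r2 += d * d;
        if (r2 >= c2) break;
      }
      if (r2 < c2) { ei.push_back(mol[i]); ej.push_back(mol[j]); }
    }
  IntegerMatrix out(ei.size(), 2);
  for (size_t k = 0; k < ei.size(); ++k) {
    out(k, 0) = ei[k];
    out(k, 1) = ej[k];
  }
  return out;
}
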