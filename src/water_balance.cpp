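#include <Rcpp.h>
using namespace Rcpp;

// Daily tipping-bucket water balance over a layered soil profile.
//
// Units: all water fluxes and storages in cm of water; theta in cm3/cm3.
// Within-day order:
// (1) infiltration: precipitation + irrigation fill the layers top-down up
//     to saturation (flood irrigation soaks in over the day); water left
//     over once the whole profile is saturated ponds and is lost as
//     surface runoff;
// (2) redistribution: each layer drains its storage above field capacity
//     downward at the conductivity-scaled rate
//        drain = excess * Ks/(Ks + thick) * s,   s = (theta-FC)/(SAT-FC),
//     additionally capped by Ks (one day's percolation) and by the
//     receiving layer's remaining pore space; the bottom layer drains
//     freely out of the 180 cm profile;
// (3) evapotranspiration: evaporation from layer 1 (down to an air-dry
//     floor of 0.5*PWP) and transpiration over the root zone, limited by
//     plant-available water (theta - PWP)+ per layer.
// End-of-day theta is recorded; theta stays in [0, SAT] by construction
// and the daily ledger closes exactly.
//
// [[Rcpp::export(name = ".water_balance_cpp")]]
List water_balance_cpp(NumericVector thick_cm,
                       NumericVector ks, NumericVector sat,
                       NumericVector fc, NumericVector pwp,
                       NumericVector theta0,
                       NumericVector water_in_cm,   // precip + irrigation, per day
                       NumericVector evap_cm,       // potential soil evaporation
                       NumericVector transp_cm,     // potential transpiration
                       NumericVector root_depth_cm) // rooting depth per day
{
  const int nl = thick_cm.size();
  const int nd = water_in_cm.size();
  const double evap_floor_frac = 0.5; // evaporation can dry layer 1 to 0.5*PWP

  NumericVector z_top(nl), z_bot(nl);
  double z = 0.0;
  for (int i = 0; i < nl; ++i) { z_top[i] = z; z += thick_cm[i]; z_bot[i] = z; }

  std::vector<double> th(theta0.begin(), theta0.end());
  NumericMatrix theta(nd, nl);
  NumericVector runoff(nd), drain(nd), et_act(nd), storage(nd);

  for (int t = 0; t < nd; ++t) {
    // (1) infiltration fills the profile top-down to saturation
    double w = water_in_cm[t];
    for (int i = 0; i < nl && w > 0.0; ++i) {
      double cap = (sat[i] - th[i]) * thick_cm[i];
      if (cap <= 0.0) continue;
      double add = std::min(w, cap);
      th[i] += add / thick_cm[i];
      w -= add;
    }
    runoff[t] = w; // profile saturated: the rest ponds and runs off
    // (2) top-down redistribution of storage above field capacity
    for (int i = 0; i < nl; ++i) {
      double excess = (th[i] - fc[i]) * thick_cm[i];
      if (excess <= 0.0) continue;
      double s = (th[i] - fc[i]) / (sat[i] - fc[i]);
      if (s > 1.0) s = 1.0;
      double d = excess * (ks[i] / (ks[i] + thick_cm[i])) * s;
      d = std::min(d, ks[i]); // Ks caps one day's percolation
      if (i < nl - 1) {
        double cap = (sat[i + 1] - th[i + 1]) * thick_cm[i + 1];
        if (cap < 0.0) cap = 0.0;
        d = std::min(d, cap);
        th[i + 1] += d / thick_cm[i + 1];
      } else {
        drain[t] = d; // leaves the 180 cm profile
      }
      th[i] -= d / thick_cm[i];
    }
    // (3a) soil evaporation from layer 1
    double e_avail = (th[0] - evap_floor_frac * pwp[0]) * thick_cm[0];
    if (e_avail < 0.0) e_avail = 0.0;
    double e_act = std::min(evap_cm[t], e_avail);
    th[0] -= e_act / thick_cm[0];
    // (3b) transpiration over the root zone, weighted by available water
    double t_act = 0.0;
    if (transp_cm[t] > 0.0 && root_depth_cm[t] > 0.0) {
      std::vector<double> avail(nl, 0.0);
      double tot = 0.0;
      for (int i = 0; i < nl; ++i) {
        double ov = std::min(z_bot[i], root_depth_cm[t]) - z_top[i];
        if (ov <= 0.0) continue;
        double a = (th[i] - pwp[i]) * thick_cm[i] * (ov / thick_cm[i]);
        if (a > 0.0) { avail[i] = a; tot += a; }
      }
      if (tot > 0.0) {
        t_act = std::min(transp_cm[t], tot);
        for (int i = 0; i < nl; ++i)
          if (avail[i] > 0.0) th[i] -= (t_act * avail[i] / tot) / thick_cm[i];
      }
    }
    et_act[t] = e_act + t_act;

    double s = 0.0;
    for (int i = 0; i < nl; ++i) { theta(t, i) = th[i]; s += th[i] * thick_cm[i]; }
    storage[t] = s;
  }

  return List::create(_["theta"] = theta, _["runoff"] = runoff,
                      _["drainage"] = drain, _["et_act"] = et_act,
                      _["storage"] = storage);
}
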