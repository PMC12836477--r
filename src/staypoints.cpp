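#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Haversine distance on a sphere of radius 6,371,000 m; sub-meter error at
// the 150-m scale the stay-point rule operates on.
static double hav_m(double lat1, double lon1, double lat2, double lon2) {
    const double R = 6371000.0, d2r = M_PI / 180.0;
    double dlat = (lat2 - lat1) * d2r * 0.5;
    double dlon = (lon2 - lon1) * d2r * 0.5;
    double a = std::sin(dlat) * std::sin(dlat) +
               std::cos(lat1 * d2r) * std::cos(lat2 * d2r) *
               std::sin(dlon) * std::sin(dlon);
    double s = std::sqrt(a);
    if (s > 1.0) s = 1.0;
    return 2.0 * R * std::asin(s);
}

// Sequential-scan stay-point detector. Anchor at i; advance j while
// p_j stays within dist_m of the anchor p_i; when the window i..j-1 spans
// at least min_dur_s, emit its centroid and restart at j, otherwise slide
// the anchor forward by one.
// [[Rcpp::export(name = ".scan_stay_points")]]
DataFrame scan_stay_points_cpp(NumericVector ts, NumericVector lat,
                               NumericVector lon, double dist_m,
                               double min_dur_s) {
    int n = ts.size();
    std::vector<int> si, ei;
    std::vector<double> clat, clon, at, dt;
    int i = 0;
    while (i < n - 1) {
        int j = i + 1;
        while (j < n && hav_m(lat[i], lon[i], lat[j], lon[j]) <= dist_m) j++;
        if (ts[j - 1] - ts[i] >= min_dur_s) {
            double sl = 0.0, so = 0.0;
            for (int k = i; k < j; k++) { sl += lat[k]; so += lon[k]; }
            si.push_back(i + 1);           // 1-based for R
            ei.push_back(j);
            clat.push_back(sl / (j - i));
            clon.push_back(so / (j - i));
            at.push_back(ts[i]);
            dt.push_back(ts[j - 1]);
            i = j;
        } else {
            i++;
        }
    }
    return DataFrame::create(
        _["centroid_lat"] = clat, _["centroid_lon"] = clon,
        _["arrival_ts"] = at, _["departure_ts"] = dt,
        _["start_idx"] = si, _["end_idx"] = ei);
}
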