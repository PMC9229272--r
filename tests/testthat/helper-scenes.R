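# Parameterised synthetic scenes used across the suite. All deterministic
# given their seed.

# the reference recording: textured out-of-plane ellipsoid, 86 rpm, 159
# frames at 15 fps, vignetting, debris and noise
scene_reference <- function(rpm = 86, seed = 1, n_frames = 159, fps = 15,
                            noise_sigma = 2, vignette = 0.3) {
  render_video(scene_config(
    width = 96, height = 96, n_frames = n_frames, fps = fps,
    cells = list(cell_spec(semi_axes = c(12, 12, 8), rotation_rpm = rpm)),
    vignette_strength = vignette, noise_sigma = noise_sigma, rng_seed = seed
  ))
}

# clean scene: no vignette, no noise, no debris -- for exact-geometry checks
scene_clean <- function(cells, n_frames = 12, width = 64, height = 64, fps = 15,
                        seed = 1) {
  render_video(scene_config(
    width = width, height = height, n_frames = n_frames, fps = fps,
    cells = cells, vignette_strength = 0, noise_sigma = 0, n_debris = 0,
    rng_seed = seed
  ))
}

# spot-textured sphere rotating in-plane (quarter-box scenario)
scene_inplane <- function(rpm = 60, seed = 3, n_frames = 159) {
  render_video(scene_config(
    width = 96, height = 96, n_frames = n_frames, fps = 15,
    cells = list(cell_spec(semi_axes = c(14, 14, 14), rotation_rpm = rpm,
                           rotation_mode = "in_plane", n_spots = 1,
                           spot_contrast = -60, spot_radius = 4)),
    vignette_strength = 0.3, noise_sigma = 2, rng_seed = seed
  ))
}

# homogeneous sphere with one dark internal spot rotating out of plane:
# constant outline, area dips once per revolution (symmetry factor 1)
scene_spot_sphere <- function(rpm = 150, seed = 4, n_frames = 159) {
  render_video(scene_config(
    width = 96, height = 96, n_frames = n_frames, fps = 15,
    cells = list(cell_spec(semi_axes = c(13, 13, 13), rotation_rpm = rpm,
                           n_spots = 1, spot_contrast = -70, spot_radius = 3.5)),
    vignette_strength = 0.3, noise_sigma = 2, rng_seed = seed
  ))
}

# cell-free vignetted frame for correction checks
frame_cellfree <- function(strength = 0.3, noise_sigma = 2, seed = 5,
                           width = 96, height = 96) {
  cfg <- scene_config(width = width, height = height, n_frames = 2,
                      cells = list(), vignette_strength = strength,
                      noise_sigma = noise_sigma, n_debris = 0, rng_seed = seed)
  render_frame(cfg, 1)
}

rms_vs_truth <- function(traj, truth) {
  sqrt(mean((traj$row - truth$row[traj$frame])^2 +
              (traj$col - truth$col[traj$frame])^2))
}
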