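frame,keypoint,x,y,z,valid
1,1,0,710.6,10.2,TRUE
1,2,30.6,729.64,13.6,TRUE
1,3,-30.6,729.64,13.6,TRUE
1,4,71.4,717.4,-71.4,TRUE
1,5,-71.4,717.4,-71.4,TRUE
1,6,195.5,489.6,0,TRUE
1,7,-195.5,489.6,0,TRUE
1,8,511.7,489.6,0,TRUE
1,9,-511.7,489.6,0,TRUE
1,10,759.9,489.6,0,TRUE
1,11,-759.9,489.6,0,TRUE
1,12,102,0,0,TRUE
1,13,-102,0,0,TRUE
1,14,102,-416.5,0,TRUE
1,15,-102,-416.5,0,TRUE
1,16,102,-834.7,0,TRUE
1,17,-102,-834.7,0,TRUE
1,18,122.672,-901,193.8,TRUE
1,19,70.992,-901,180.88,TRUE
1,20,102,-901,-64.6,TRUE
1,21,-122.672,-901,193.8,TRUE
1,22,-70.992,-901,180.88,TRUE
1,23,-102,-901,-64.6,TRUE
1,24,-71.4,693.6,-13.6,TRUE
1,25,-70.028,680.997,-3.65,TRUE
1,26,-65.965,668.879,5.917,TRUE
1,27,-59.367,657.71,14.734,TRUE
1,28,-50.487,647.921,22.462,TRUE
1,29,-39.668,639.887,28.805,TRUE
1,30,-27.324,633.917,33.518,TRUE
1,31,-13.929,630.241,36.42,TRUE
1,32,0,629,37.4,TRUE
1,33,13.929,630.241,36.42,TRUE
1,34,27.324,633.917,33.518,TRUE
1,35,39.668,639.887,28.805,TRUE
1,36,50.487,647.921,22.462,TRUE
1,37,59.367,657.71,14.734,TRUE
1,38,65.965,668.879,5.917,TRUE
1,39,70.028,680.997,-3.65,TRUE
1,40,71.4,693.6,-13.6,TRUE
1,41,-57.8,741.2,27.2,TRUE
1,42,-45.9,746.97,27.2,TRUE
1,43,-34,749.36,27.2,TRUE
1,44,-22.1,746.97,27.2,TRUE
1,45,-10.2,741.2,27.2,TRUE
1,46,10.2,741.2,27.2,TRUE
1,47,22.1,746.97,27.2,TRUE
1,48,34,749.36,27.2,TRUE
1,49,45.9,746.97,27.2,TRUE
1,50,57.8,741.2,27.2,TRUE
1,51,0,734.4,20.4,TRUE
1,52,0,726.92,23.8,TRUE
1,53,0,719.44,27.2,TRUE
1,54,0,711.96,30.6,TRUE
1,55,-14.96,701.08,22.44,TRUE
1,56,-7.48,701.08,22.44,TRUE
1,57,0,698.36,22.44,TRUE
1,58,7.48,701.08,22.44,TRUE
1,59,14.96,701.08,22.44,TRUE
1,60,-49.64,729.64,13.6,TRUE
1,61,-40.12,735.76,13.6,TRUE
1,62,-22.44,735.76,13.6,TRUE
1,63,-12.92,729.64,13.6,TRUE
1,64,-22.44,724.2,13.6,TRUE
1,65,-40.12,724.2,13.6,TRUE
1,66,12.92,729.64,13.6,TRUE
1,67,22.44,735.76,13.6,TRUE
1,68,40.12,735.76,13.6,TRUE
1,69,49.64,729.64,13.6,TRUE
1,70,40.12,724.2,13.6,TRUE
1,71,22.44,724.2,13.6,TRUE
1,72,-28.56,673.2,18.36,TRUE
1,73,-24.734,679.32,18.36,TRUE
1,74,-12.07,684.293,18.36,TRUE
1,75,0,685.44,18.36,TRUE
1,76,12.07,684.293,18.36,TRUE
1,77,24.734,679.32,18.36,TRUE
1,78,28.56,673.2,18.36,TRUE
1,79,24.734,667.08,18.36,TRUE
1,80,12.07,662.107,18.36,TRUE
1,81,0,660.96,18.36,TRUE
1,82,-12.07,662.107,18.36,TRUE
1,83,-24.734,667.08,18.36,TRUE
1,84,-17,673.2,18.36,TRUE
1,85,-8.5,678.5,18.36,TRUE
1,86,0,679.32,18.36,TRUE
1,87,8.5,678.5,18.36,TRUE
1,88,17,673.2,18.36,TRUE
1,89,8.5,667.9,18.36,TRUE
1,90,0,667.08,18.36,TRUE
1,91,-8.5,667.9,18.36,TRUE
1,92,759.9,489.6,0,TRUE
1,93,794.618,499.244,-54.006,TRUE
1,94,825.479,505.03,-81.009,TRUE
1,95,848.624,508.888,-100.297,TRUE
1,96,865.983,510.817,-111.87,TRUE
1,97,846.695,489.6,-34.718,TRUE
1,98,891.058,489.6,-34.718,TRUE
1,99,921.918,489.6,-34.718,TRUE
1,100,943.135,489.6,-34.718,TRUE
1,101,846.695,489.6,-11.573,TRUE
1,102,891.058,489.6,-11.573,TRUE
1,103,921.918,489.6,-11.573,TRUE
1,104,943.135,489.6,-11.573,TRUE
1,105,846.695,489.6,11.573,TRUE
1,106,891.058,489.6,11.573,TRUE
1,107,921.918,489.6,11.573,TRUE
1,108,943.135,489.6,11.573,TRUE
1,109,846.695,489.6,34.718,TRUE
1,110,891.058,489.6,34.718,TRUE
1,111,921.918,489.6,34.718,TRUE
1,112,943.135,489.6,34.718,TRUE
1,113,-759.9,489.6,0,TRUE
1,114,-794.618,499.244,-54.006,TRUE
1,115,-825.479,505.03,-81.009,TRUE
1,116,-848.624,508.888,-100.297,TRUE
1,117,-865.983,510.817,-111.87,TRUE
1,118,-846.695,489.6,-34.718,TRUE
1,119,-891.058,489.6,-34.718,TRUE
1,120,-921.918,489.6,-34.718,TRUE
1,121,-943.135,489.6,-34.718,TRUE
1,122,-846.695,489.6,-11.573,TRUE
1,123,-891.058,489.6,-11.573,TRUE
1,124,-921.918,489.6,-11.573,TRUE
1,125,-943.135,489.6,-11.573,TRUE
1,126,-846.695,489.6,11.573,TRUE
1,127,-891.058,489.6,11.573,TRUE
1,128,-921.918,489.6,11.573,TRUE
1,129,-943.135,489.6,11.573,TRUE
1,130,-846.695,489.6,34.718,TRUE
1,131,-891.058,489.6,34.718,TRUE
1,132,-921.918,489.6,34.718,TRUE
1,133,-943.135,489.6,34.718,TRUE
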