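id,species,group,nutrient,response_var,A,c,b,B,printed_r_max,printed_nutrient_star,printed_response_star,printed_nutrient_lag,printed_half_life,printed_response_inf,printed_req95,printed_req99,printed_r2,printed_rmse
1_broilers,broilers,broilers,lysine (g/kg diet),body weight gain (g/bird),235.9,0.510,-4.34,297.0,120.5,8.48,296.4,6.55,8.22,532.2,11.2,12.9,0.961,39.8
1_layers,layers,layers,lysine (g/kg diet),body weight gain (g/bird),57.9,0.462,-3.11,96.2,27.3,6.72,96.6,4.83,5.96,153.9,9.5,11.3,0.913,13.1
2_broilers,broilers,broilers,lysine (g/kg diet),feed efficiency (g/g),0.237,0.389,-2.93,0.588,0.092,7.49,0.586,5.19,4.99,0.823,10.5,12.7,0.886,0.062
2_layers,layers,layers,lysine (g/kg diet),feed efficiency (g/g),0.169,0.431,-3.25,0.545,0.073,7.47,0.541,5.24,3.59,0.718,10.3,12.4,0.632,0.081
3_broilers,broilers,broilers,lysine (g/kg diet),protein accretion (g/bird),38.21,0.509,-4.38,48.8,19.6,8.6,48.7,6.68,8.33,86.9,11.3,13,0.950,7.30
3_layers,layers,layers,lysine (g/kg diet),protein accretion (g/bird),10.4,0.470,-3.22,18.6,4.85,6.84,18.5,4.9,5.95,28.9,9.64,11.4,0.939,1.99
4_broilers,broilers,broilers,lysine (g/kg diet),lysine accretion (g/bird),2.72,0.478,-4.25,3.21,1.32,8.89,3.21,6.86,8.71,5.93,11.8,13.6,0.968,0.417
4_layers,layers,layers,lysine (g/kg diet),lysine accretion (g/bird),0.641,0.412,-2.84,0.928,0.261,6.87,0.923,4.72,6.33,1.57,10.3,12.3,0.950,0.108
5_broilers,broilers,broilers,lysine (g/kg diet),energy accretion (MJ/bird),2.15,0.486,-4.20,2.66,1.04,8.65,2.65,6.61,8.4,4.8,11.6,13.3,0.967,0.329
5_layers,layers,layers,lysine (g/kg diet),energy accretion (MJ/bird),0.431,0.401,-2.48,0.629,0.174,5.99,0.601,4.13,5.59,1.06,9.73,11.9,0.898,0.096
6_broilers,broilers,broilers,lysine (g/kg diet),energy utilization efficiency (%),12.30,0.377,-2.97,29.1,4.59,7.85,28.9,5.37,5.69,41.5,11.2,13.6,0.862,3.56
6_layers,layers,layers,lysine (g/kg diet),energy utilization efficiency (%),11.4,0.224,-1.10,16.2,2.54,5.09,16.5,3.75,3.82,27.7,11.1,14.8,0.623,3.20
7_LP,broilers,LP,methionine (g/kg diet),protein accretion (g/bird),32.4,1.91,-5.14,54.6,62.8,2.69,54.4,2.19,2.5,86.9,3.37,3.8,0.944,6.12
7_NP,broilers,NP,methionine (g/kg diet),protein accretion (g/bird),32.0,2.19,-6.21,50.0,68.3,2.83,49.9,2.37,2.7,82,3.47,3.86,0.940,6.62
8_week1,ducks,week1,valine (g/kg diet),body weight (g/duck),56.4,1.42,-10.4,229.3,78.6,7.31,225.9,6.69,6.37,285.5,8.07,8.73,0.921,10.0
8_week2,ducks,week2,valine (g/kg diet),body weight (g/duck),117.6,1.97,-14.79,712.2,245.6,7.5,711.5,7.1,6.83,829,7.88,8.32,0.863,25.2
8_week3,ducks,week3,valine (g/kg diet),body weight (g/duck),238.8,2.40,-18.1,1283.4,579.4,7.49,1265,7.09,6.78,1524.8,7.9,8.3,0.910,46.8
9_broilers,broilers,broilers,valine (g/kg diet),weight gain (g),236.1,1.10,-7.23,348.9,257,6.56,345.7,5.79,6.35,585.5,7.84,8.62,0.965,32.0
10_hens,laying hens,hens,threonine (mg/bird),egg mass (g),33.2,0.006,-0.945,17.1,0.191,170,18.2,148.2,206.2,50.3,443,584.1,0.801,2.59
11_broilers,broilers,broilers,phosphorus (g/kg diet),phosphorus accretion (mg/d),236.9,0.303,-0.797,97.6,72.4,2.83,111.3,2.75,3.63,334.7,8.08,10.8,0.917,20.0
11_ducks,ducks,ducks,phosphorus (g/kg diet),phosphorus accretion (mg/d),301.8,0.412,-1.68,310.7,124.9,4.06,308.4,2.9,4.05,612.9,7.65,9.67,0.959,30.0
11_quails,quails,quails,phosphorus (g/kg diet),phosphorus accretion (mg/d),33.1,0.755,-2.06,33.8,24.8,2.91,38,2.8,2.79,66.8,4.62,5.66,0.671,5.75
12_trout,rainbow trout,trout,phosphorus (g/kg diet),weight gain (g/fish),57.5,1.17,-2.12,86.8,68.9,1.81,87,1.19,1.59,144.3,2.95,3.65,0.954,7.07
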