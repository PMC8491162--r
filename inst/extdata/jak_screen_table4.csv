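id,df_gen,df1,class1,df2,class2,df3,class3,tested
AA-516/30011028,1.370,4.408,JAK1,5.096,JAK2,-7.554,,TRUE
AB-323/13887443,0.996,4.940,JAK1,-2.528,,-3.924,,FALSE
AC-907/34131030,1.729,1.524,JAK1*,3.415,JAK2,-5.154,,FALSE
AE-848/34779061,1.682,1.830,JAK1*,0.956,,-5.407,,FALSE
AF-399/13277002,2.313,1.661,JAK1*,-9.474,,34.181,N.C.,FALSE
AF-399/13426006,1.013,8.821,N.C.,6.795,N.C.,-6.897,,FALSE
AF-399/15031149,1.546,0.951,JAK1*,-0.561,,-5.680,,FALSE
AF-399/15032375,0.981,5.213,JAK1,-0.973,,-7.423,,FALSE
AF-399/33696009,1.977,5.731,JAK1,2.553,JAK2,-3.293,,FALSE
AF-399/37297037,1.454,-2.344,,-2.130,,-0.599,,FALSE
AF-399/41668884,1.270,6.604,JAK1,2.890,JAK2,-7.146,,FALSE
AF-399/41945530,1.875,0.214,JAK1*,2.056,JAK2,-2.432,,FALSE
AF-399/42056988,0.978,2.044,JAK1*,5.767,JAK2,4.314,JAK3,FALSE
AF-399/42100326,1.649,4.054,JAK1,2.115,JAK2,-4.967,,TRUE
AF-399/42762404,1.901,5.191,JAK1,3.680,JAK2,-8.082,,FALSE
AG-205/11444099,0.921,2.650,JAK1,6.925,N.C.,7.388,JAK3,FALSE
AG-205/11674118,0.993,1.653,JAK1*,2.922,JAK2,7.297,JAK3,FALSE
AG-205/12010072,0.954,4.327,JAK1,1.075,JAK2,-3.811,,TRUE
AG-205/14250132,0.508,1.765,JAK1*,-3.150,,-4.043,,FALSE
AG-205/14673025,1.414,1.456,JAK1*,2.119,JAK2,-0.373,,FALSE
AG-401/02041003,1.810,-3.699,,-5.515,,3.404,JAK3,FALSE
AG-670/13619018,-0.978,3.426,JAK1,3.325,JAK2,-0.314,,TRUE
AG-690/36926024,2.249,-2.545,,-0.516,JAK2,4.618,JAK3,FALSE
AH-357/03329001,0.530,0.563,JAK1*,0.175,JAK2,-5.608,,FALSE
AK-778/43206447,2.346,0.171,JAK1*,5.559,JAK2,-0.863,,TRUE
AK-968/15359231,2.103,3.603,JAK1,3.093,JAK2,-4.128,,FALSE
AM-807/37225018,0.646,11.083,N.C.,1.879,JAK2,-16.247,,FALSE
AN-329/11658808,2.503,2.659,JAK1,4.496,JAK2,0.445,JAK3,FALSE
AN-329/41717385,-1.097,7.420,JAK1,3.673,JAK2,-5.092,,FALSE
AN-584/40652663,2.879,7.470,JAK1,7.042,N.C.,5.262,JAK3,FALSE
AN-584/43492329,1.641,3.542,JAK1,3.279,JAK2,6.518,JAK3,FALSE
AN-988/41531688,0.663,-1.129,JAK1*,4.160,JAK2,-3.345,,FALSE
AO-365/43473564,1.559,4.322,JAK1,-0.516,JAK2,5.543,JAK3,FALSE
AO-476/41610187,1.340,0.351,JAK1*,-9.178,,3.540,JAK3,TRUE
AO-476/43250148,1.253,5.967,JAK1,-2.347,,0.294,JAK3,FALSE
AO-476/43250150,2.215,6.816,JAK1,-1.103,,-2.306,,FALSE
AO-476/43250160,1.120,6.705,JAK1,-1.464,,-3.291,,FALSE
AO-476/43417077,1.690,-1.031,JAK1*,3.833,JAK2,1.214,JAK3,TRUE
AP-064/42049177,0.803,-6.558,,-0.021,JAK2,1.564,JAK3,FALSE
AP-501/43286814,1.120,-0.082,JAK1*,1.093,JAK2,-4.604,,FALSE
AQ-405/42300191,0.548,0.990,JAK1*,5.571,JAK2,-2.172,,TRUE
AQ-432/43399984,0.528,5.710,JAK1,3.595,JAK2,-5.423,,FALSE
AQ-432/43400108,1.617,2.557,JAK1,4.888,JAK2,0.677,JAK3,FALSE
AQ-432/43400219,0.862,0.113,JAK1*,3.845,JAK2,2.936,JAK3,FALSE
AQ-432/43400304,0.772,5.631,JAK1,3.870,JAK2,-5.792,,FALSE
AQ-432/43400319,1.602,2.562,JAK1,4.251,JAK2,3.808,JAK3,FALSE
AT-417/43503979,0.903,3.253,JAK1,8.632,N.C.,20.232,N.C.,FALSE
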