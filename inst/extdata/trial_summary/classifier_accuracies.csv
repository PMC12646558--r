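group,week,classifier,accuracy
experimental,0,knn,39.98
experimental,0,random_forest,36.85
experimental,0,svm,34.91
experimental,4,knn,57.05
experimental,4,random_forest,53.03
experimental,4,svm,52.05
experimental,6,knn,83.18
experimental,6,random_forest,81.57
experimental,6,svm,80.50
experimental,9,knn,84.68
experimental,9,random_forest,83.52
experimental,9,svm,82.56
control,0,knn,40.05
control,0,random_forest,37.28
control,0,svm,35.15
control,4,knn,54.85
control,4,random_forest,51.63
control,4,svm,50.33
control,6,knn,77.95
control,6,random_forest,77.78
control,6,svm,76.32
control,9,knn,79.64
control,9,random_forest,79.72
control,9,svm,78.25
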